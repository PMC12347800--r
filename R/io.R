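# Atom/residue naming used when writing synthetic ensembles to GRO, and the
# default mapping back to species tags when reading.

#' Default selection specification
#'
#' Maps residue names (and atom-name prefixes within lipid residues) to the
#' package's species tags. Used by [read_trajectory()] and [read_gro()];
#' supply your own list of the same shape for other naming schemes.
#'
#' @return named list: `lipid_resname`, `water_resnames`, `ion_resnames`,
#'   `solute_resnames`, plus lipid atom-name prefixes `head_prefix`,
#'   `carbon_prefix`, `hydrogen_prefix`.
#' @export
default_selection_spec <- function() {
  list(lipid_resname = "LIP",
       water_resnames = c("SOL", "TIP3", "HOH", "WAT"),
       ion_resnames = c("NA", "CL", "SOD", "CLA", "K", "MG"),
       solute_resnames = c("SLT", "LIG", "UNK"),
       head_prefix = "HD", carbon_prefix = "C", hydrogen_prefix = "H")
}

# Electron counts by element symbol, for coordinate files that do not carry
# explicit electron metadata.
ELEMENT_ELECTRONS <- c(H = 1, C = 6, N = 7, O = 8, NA2 = 11, MG = 12, P = 15,
                       S = 16, CL = 17, K = 19)

#' Write an ensemble to a (multi-frame) GRO file
#'
#' Fixed-column GRO dialect, coordinates in nm; frames are concatenated
#' blocks. Atom names encode the synthetic topology (`HD` head bead, `Cnn`
#' tail carbons, `Hnn[A|B]` their hydrogens) so that [read_gro()]
#' reconstructs species tags, chain indices and hydrogen-carbon links. A
#' JSON sidecar (`<path>.json`) stores the ground-truth parameters when the
#' ensemble carries them.
#'
#' @param ensemble a [particle_ensemble()].
#' @param path output `.gro` path.
#' @param sidecar write the ground-truth JSON sidecar if available
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_gro <- function(ensemble, path, sidecar = TRUE) {
  p <- ensemble$particles
  nm <- character(nrow(p))
  res <- p$residue
  resname <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    resname[i] <- switch(p$species[i],
                         "lipid-head" = , "lipid-tail-carbon" = ,
                         "tail-hydrogen" = "LIP",
                         water = "SOL", ion = "ION", solute = "SLT")
    nm[i] <- switch(p$species[i],
      "lipid-head" = "HD",
      "lipid-tail-carbon" = sprintf("C%02d", p$carbon_index[i]),
      "tail-hydrogen" = sprintf("H%02d", p$carbon_index[i]),
      water = "OW", ion = "ION", solute = "SU")
  }
  # disambiguate the two hydrogens of a carbon as A/B (pairs are consecutive)
  hyd <- which(p$species == "tail-hydrogen")
  if (length(hyd))
    nm[hyd] <- paste0(nm[hyd], rep(c("A", "B"), length.out = length(hyd)))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(ensemble$frames)) {
    xyz <- ensemble$frames[[f]]
    writeLines(sprintf("synthetic bilayer frame %d", f), con)
    writeLines(sprintf("%5d", nrow(p)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res %% 100000L, resname, substr(nm, 1, 5),
                     seq_len(nrow(p)) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", ensemble$box[f, 1],
                       ensemble$box[f, 2], ensemble$box[f, 3]), con)
  }
  gt <- attr(ensemble, "ground_truth")
  if (sidecar && !is.null(gt)) {
    gt$solute_pmf <- if (is.function(gt$solute_pmf)) "function" else
      gt$solute_pmf
    gt$counts <- as.list(gt$counts) # keep names through JSON
    jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a (multi-frame) GRO file into a particle ensemble
#'
#' @param path `.gro` file (possibly concatenated frames).
#' @param selection_spec mapping from residue/atom names to species tags;
#'   see [default_selection_spec()].
#' @return a [particle_ensemble()].
#' @export
read_gro <- function(path, selection_spec = default_selection_spec()) {
  lines <- readLines(path)
  frames <- list(); boxes <- NULL; meta <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines) || !nzchar(trimws(lines[i + 1L]))) break
    n <- as.integer(trimws(lines[i + 1L]))
    body <- lines[(i + 2L):(i + 1L + n)]
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    xyz <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44)))
    if (is.null(meta)) {
      resid <- as.integer(substr(body, 1, 5))
      resname <- trimws(substr(body, 6, 10))
      atom <- trimws(substr(body, 11, 15))
      meta <- gro_metadata(resid, resname, atom, xyz, box, selection_spec)
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes <- rbind(boxes, box)
    i <- i + 3L + n
  }
  ens <- particle_ensemble(frames, boxes, meta)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(ens, "ground_truth") <- jsonlite::read_json(side, simplifyVector = TRUE)
  ens
}

# Build the particle metadata table from GRO naming.
gro_metadata <- function(resid, resname, atom, xyz, box, spec) {
  n <- length(resid)
  species <- rep(NA_character_, n)
  cindex <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  is_lip <- resname == spec$lipid_resname
  species[resname %in% spec$water_resnames] <- "water"
  species[resname %in% spec$ion_resnames | resname == "ION"] <- "ion"
  species[resname %in% spec$solute_resnames] <- "solute"
  species[is_lip & startsWith(atom, spec$head_prefix)] <- "lipid-head"
  is_c <- is_lip & grepl("^C[0-9]+$", atom)
  is_h <- is_lip & grepl("^H[0-9]+[A-Z]?$", atom)
  species[is_c] <- "lipid-tail-carbon"
  species[is_h] <- "tail-hydrogen"
  cindex[is_c] <- as.integer(sub("^C", "", atom[is_c]))
  cindex[is_h] <- as.integer(gsub("[^0-9]", "", atom[is_h]))
  if (anyNA(species)) {
    bad <- unique(paste(resname, atom)[is.na(species)])
    stop("unmapped atoms: ", paste(bad, collapse = ", "))
  }
  # hydrogen -> parent carbon: same residue, same chain index
  key_c <- paste(resid, cindex)[is_c]
  lookup <- stats::setNames(which(is_c), key_c)
  parent[is_h] <- lookup[paste(resid, cindex)[is_h]]
  # leaflet from z relative to the lipid mass center
  mass <- rep(BEAD_PROPS$solute$mass, n)
  elec <- rep(BEAD_PROPS$solute$electrons, n)
  assign_props <- function(tag, props) {
    mass[species == tag] <<- props$mass
    elec[species == tag] <<- props$electrons
  }
  assign_props("lipid-head", BEAD_PROPS$head)
  assign_props("lipid-tail-carbon", BEAD_PROPS$carbon)
  assign_props("tail-hydrogen", BEAD_PROPS$hydrogen)
  assign_props("water", BEAD_PROPS$water)
  assign_props("ion", BEAD_PROPS$sodium)
  lipsel <- species %in% LIPID_SPECIES
  com <- sum(mass[lipsel] * xyz[lipsel, 3]) / sum(mass[lipsel])
  leaflet <- rep("none", n)
  leaflet[lipsel] <- ifelse(xyz[lipsel, 3] >= com, "upper", "lower")
  data.frame(species = species, mass = mass, electron_count = elec,
             residue = resid, leaflet = leaflet, carbon_index = cindex,
             parent = parent, stringsAsFactors = FALSE)
}

#' Read coordinates (plus an optional trajectory) into an ensemble
#'
#' Supported coordinate formats: GRO (native reader) and PDB (via bio3d,
#' Angstrom converted to nm). An optional DCD trajectory (bio3d) replaces
#' the frames. Triclinic boxes are rejected; only orthorhombic cells are
#' supported. XTC input is not supported by the available readers - convert
#' to DCD or multi-frame GRO first.
#'
#' @param coord_path `.gro` or `.pdb` file.
#' @param traj_path optional `.dcd` trajectory.
#' @param selection_spec see [default_selection_spec()].
#' @return a [particle_ensemble()].
#' @export
read_trajectory <- function(coord_path, traj_path = NULL,
                            selection_spec = default_selection_spec()) {
  ext <- tolower(tools::file_ext(coord_path))
  if (ext == "gro") {
    ens <- read_gro(coord_path, selection_spec)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(coord_path)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    resname <- trimws(pdb$atom$resid)
    atom <- trimws(pdb$atom$elety)
    resid <- pdb$atom$resno
    box <- apply(xyz, 2, function(v) diff(range(v))) + 0.2
    meta <- gro_metadata(resid, resname, atom, xyz, box, selection_spec)
    ens <- particle_ensemble(list(xyz), matrix(box, 1), meta)
  } else stop("unsupported coordinate format: .", ext,
              " (use GRO or PDB)")
  if (!is.null(traj_path)) {
    text <- tolower(tools::file_ext(traj_path))
    if (text == "xtc")
      stop("XTC trajectories are unsupported; convert to DCD or multi-frame GRO")
    if (text != "dcd") stop("unsupported trajectory format: .", text)
    dcd <- bio3d::read.dcd(traj_path, cell = FALSE, verbose = FALSE)
    frames <- lapply(seq_len(nrow(dcd)), function(i)
      matrix(dcd[i, ], ncol = 3, byrow = TRUE) / 10)
    box <- matrix(rep(ens$box[1, ], each = length(frames)), ncol = 3)
    ens <- particle_ensemble(frames, box, ens$particles)
  }
  ens
}

#' Run configuration for the analysis pipeline
#'
#' Builds and validates a pipeline configuration, either programmatically or
#' from a YAML file. Simulation temperatures default to the study
#' conventions (330 K for PC/PG-like systems, 345 K for PE/PA-like systems)
#' but any positive value is accepted.
#'
#' @param builder named list of [bilayer_spec()] arguments (synthetic
#'   input), or `NULL` when reading files.
#' @param coord_path,traj_path input files (alternative to `builder`).
#' @param temperature K.
#' @param bin_width density histogram bin width, nm.
#' @param bulk_margin margin beyond D_HH/2 defining the bulk region, nm.
#' @param smoothing_window feature-extraction smoothing window, bins.
#' @param seeds integer vector; more than one seed triggers replica PMFs.
#' @param output_dir directory for result artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(builder = NULL, coord_path = NULL, traj_path = NULL,
                       temperature = 330, bin_width = 0.02, bulk_margin = 0.5,
                       smoothing_window = 5, seeds = 1L,
                       output_dir = "memperm-out") {
  if (is.null(builder) && is.null(coord_path))
    stop("config needs either a builder spec or a coordinate path")
  if (!is.null(coord_path) && !file.exists(coord_path))
    stop("coordinate file not found: ", coord_path)
  if (!is.null(traj_path) && !file.exists(traj_path))
    stop("trajectory file not found: ", traj_path)
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(builder = builder, coord_path = coord_path,
                 traj_path = traj_path, temperature = temperature,
                 bin_width = bin_width, bulk_margin = bulk_margin,
                 smoothing_window = smoothing_window,
                 seeds = as.integer(seeds), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields above.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes density -> structure -> partition -> PMF -> features -> regions
#' on a synthetic or file-based input, writes CSV/JSON artifacts into the
#' output directory plus a JSON manifest with package version, seeds,
#' parameters, per-stage status and timings. Stages that need solute data
#' are skipped with a warning when the system has no solutes. With several
#' seeds (synthetic input), per-replica PMFs are combined into a mean +/- sd
#' profile.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "memperm",
                   version = as.character(utils::packageVersion("memperm")),
                   seeds = config$seeds,
                   parameters = config[c("temperature", "bin_width",
                                         "bulk_margin", "smoothing_window")],
                   stages = list())
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = if (is.null(attr(res, "skipped"))) "completed" else "skipped",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[memperm] %-10s %s (%.2fs)", name,
                    manifest$stages[[name]]$status,
                    manifest$stages[[name]]$seconds))
    res
  }
  out <- function(f) file.path(config$output_dir, f)

  load_ensemble <- function(seed) {
    if (!is.null(config$builder)) {
      args <- config$builder
      args$seed <- seed
      args$temperature <- config$temperature
      build_bilayer_system(do.call(bilayer_spec, args))
    } else {
      read_trajectory(config$coord_path, config$traj_path)
    }
  }
  ens <- load_ensemble(config$seeds[1])
  has_solute <- "solute" %in% ens$particles$species

  profiles <- t_stage("density", function() {
    ps <- list(
      lipid = compute_density_profile(ens, LIPID_SPECIES, "mass",
                                      config$bin_width),
      water = compute_density_profile(ens, "water", "mass", config$bin_width),
      head = compute_density_profile(ens, "lipid-head", "mass",
                                     config$bin_width),
      electron = compute_density_profile(ens, LIPID_SPECIES, "electron", 0.1))
    if (has_solute)
      ps$solute <- compute_density_profile(ens, "solute", "number",
                                           config$bin_width)
    for (nmp in names(ps)) write_profile_csv(ps[[nmp]],
                                             out(paste0("density_", nmp, ".csv")))
    ps
  })

  gt <- attr(ens, "ground_truth")
  n_lipid <- if (!is.null(gt)) as.numeric(unlist(gt$counts)["lipid"]) else
    sum(ens$particles$species == "lipid-head")
  structure_res <- t_stage("structure", function() {
    sp <- structural_params(ens, n_lipid)
    write_structural_params(sp, out("structure.csv"), out("structure.json"))
    sp
  })
  dhh <- structure_res$dhh$value

  partition_res <- t_stage("partition", function() {
    if (!has_solute) {
      warning("no solute present; partition stage skipped")
      return(structure(list(), skipped = TRUE))
    }
    pr <- partition_coefficient(profiles$solute, dhh)
    jsonlite::write_json(unclass(pr), out("partition.json"),
                         auto_unbox = TRUE, digits = NA)
    pr
  })

  pmf_res <- t_stage("pmf", function() {
    if (!has_solute) {
      warning("no solute present; PMF stage skipped")
      return(structure(list(), skipped = TRUE))
    }
    z_bulk <- dhh / 2 + config$bulk_margin
    make_pmf <- function(e) {
      prof <- compute_density_profile(e, "solute", "number", config$bin_width)
      rho0 <- estimate_bulk_density(prof, z_bulk)$rho0
      symmetrize_pmf(pmf_from_density(prof, rho0, config$temperature, z_bulk))
    }
    if (length(config$seeds) > 1 && !is.null(config$builder)) {
      reps <- lapply(config$seeds, function(s) make_pmf(load_ensemble(s)))
      pmf <- combine_replicas(reps)
    } else pmf <- make_pmf(ens)
    write_pmf_csv(pmf, out("pmf.csv"))
    pmf
  })

  t_stage("features", function() {
    if (!has_solute) return(structure(list(), skipped = TRUE))
    ft <- extract_features(pmf_res, dhh, config$smoothing_window)
    write_pmf_csv(pmf_res, out("pmf.csv"), ft, out("features.json"))
    ft
  })

  t_stage("regions", function() {
    rg <- assign_regions(profiles$lipid, profiles$water, profiles$head, dhh)
    jsonlite::write_json(as.data.frame(rg), out("regions.json"),
                         dataframe = "rows", digits = NA)
    rg
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run the toy AWH sampler from a YAML configuration
#'
#' The YAML names a test potential (`flat`, `harmonic` with `kappa`, or
#' `double_well` with `a` and `b`) plus any [awh_params()] fields (`grid` is
#' given as `grid_min`, `grid_max`, `grid_step`). Writes the PMF estimate
#' and the convergence trace as CSVs.
#'
#' @param config_path YAML file.
#' @param output_dir output directory.
#' @return invisibly, the `awh_state`.
#' @export
run_awh_toy <- function(config_path, output_dir = "awh-out") {
  y <- yaml::read_yaml(config_path)
  pot <- switch(y$potential$name,
    flat = function(z) 0 * z,
    harmonic = {
      kappa <- y$potential$kappa
      function(z) 0.5 * kappa * z^2
    },
    double_well = {
      a <- y$potential$a; b <- y$potential$b
      function(z) a * (z^2 - b^2)^2
    },
    stop("unknown potential: ", y$potential$name))
  pargs <- y[setdiff(names(y), c("potential", "grid_min", "grid_max",
                                 "grid_step"))]
  if (!is.null(y$grid_min))
    pargs$grid <- seq(y$grid_min, y$grid_max, by = y$grid_step)
  state <- awh_run(pot, do.call(awh_params, pargs))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pmf <- awh_estimate_pmf(state)
  write_pmf_csv(pmf, file.path(output_dir, "awh_pmf.csv"))
  conv <- awh_convergence(state)
  utils::write.csv(conv, file.path(output_dir, "awh_convergence.csv"),
                   row.names = FALSE)
  invisible(state)
}
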
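#' Run the demonstration analysis pipeline
#'
#' End-to-end driver: builds (or reads) an active-site structure, analyses
#' the metal site (coordination sphere, Addison tau, Jahn-Teller axis, ring
#' stacking), generates a deterministic synthetic trajectory (harmonic
#' fluctuations plus a rotamer-switch schedule on the lysine-like arm), and
#' writes the full report set: tau series, rotamer runs, RMSF and B-factor
#' profiles, PCA variance fractions and a displacement field, as TSV files
#' plus a JSON summary embedding the configuration.
#'
#' @param config list (or path to a YAML/JSON file) with any of:
#'   `input_pdb` (path; default NULL builds the toy active site),
#'   `seed` (integer, required), `out_dir` (required),
#'   `n_frames` (default 180), `sigma` (angstrom, default 0.3),
#'   `cutoff` (angstrom, default 2.6), `tau_label_thresholds` (length 2,
#'   default c(0.3, 0.7)), `displacement_threshold` (angstrom, default 3),
#'   `min_run` (default 5), `rotamer_schedule` (data.frame code/length;
#'   default pttp 80 / mtmt 60 / pttp 40), `frame_spacing_ps` (default 40).
#' @return (invisibly) list of the computed result objects; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))

  s <- if (is.null(config$input_pdb)) {
    log_msg("pipeline: building synthetic toy active site")
    make_toy_active_site()
  } else {
    log_msg("pipeline: reading %s", config$input_pdb)
    read_pdb(config$input_pdb)
  }
  metal <- which(toupper(s$atoms$element) %in% c("CU", "ZN"))[1]
  if (is.na(metal)) stop("no Cu/Zn metal atom in input structure")

  sphere <- find_coordination_sphere(s, metal, config$cutoff)
  tau <- if (length(sphere$ligands) == 5) addison_tau(sphere) else NULL
  jt <- if (length(sphere$ligands) >= 4) jahn_teller_axis(sphere) else NULL

  # synthetic dynamics: harmonic fluctuation everywhere + scheduled rotamer
  # switching of the lysine-like residue when one is present
  lys_res <- unique(s$atoms$res_id[s$atoms$res_name == "LYS"])
  schedule <- config$rotamer_schedule
  traj <- make_harmonic_traj(s, config$sigma, config$n_frames,
                             seed = config$seed,
                             frame_spacing_ps = config$frame_spacing_ps)
  rot <- NULL
  if (length(lys_res) == 1) {
    rot_traj <- make_rotamer_switch_traj(s, lys_res, schedule, jitter = 8,
                                         seed = config$seed + 1,
                                         frame_spacing_ps = config$frame_spacing_ps)
    rot <- rotamer_series(rot_traj, lys_res, min_run = config$min_run)
  }

  heavy <- which(toupper(s$atoms$element) != "H")
  taus <- tau_series(traj, metal, config$cutoff)
  rmsd_r <- rmsd_series(traj, heavy)
  rmsf_r <- rmsf_profile(traj, heavy)
  bf <- bfactor_from_rmsf(rmsf_r)
  pca_r <- pca_ca(traj, heavy)
  disp <- displacement_field(traj, selection = heavy,
                             threshold = config$displacement_threshold)

  tsv <- function(d, name) {
    utils::write.table(d, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(taus$series, "tau_series.tsv")
  tsv(rmsd_r$series, "rmsd_series.tsv")
  tsv(rmsf_r$profile, "rmsf_profile.tsv")
  tsv(bf, "bfactor.tsv")
  tsv(data.frame(mode = seq_along(pca_r$variance_fractions),
                 eigenvalue = pca_r$eigenvalues,
                 fraction = pca_r$variance_fractions), "pca_fractions.tsv")
  if (!is.null(rot)) tsv(rot$runs, "rotamer_runs.tsv")
  write_displacement_field(disp, file.path(config$out_dir, "displacement_field.tsv"))

  summary <- list(
    config = config[setdiff(names(config), "rotamer_schedule")],
    package_version = as.character(utils::packageVersion("ltqdyn")),
    n_atoms = nrow(s$atoms),
    coordination_number = length(sphere$ligands),
    tau = if (!is.null(tau)) tau$tau else NA,
    tau_label = if (!is.null(tau)) tau$label else NA,
    jahn_teller_elongation = if (!is.null(jt)) jt$elongation else NA,
    tau_series = list(mean = taus$mean, sd = taus$sd, sem = taus$sem,
                      max = taus$max, n_undefined = taus$n_undefined),
    rmsd_plateau = list(mean = rmsd_r$plateau_mean, sd = rmsd_r$plateau_sd,
                        units = rmsd_r$units),
    rmsf = list(max = rmsf_r$max, min = rmsf_r$min, mean = rmsf_r$mean,
                sd = rmsf_r$sd, units = rmsf_r$units),
    pca_fractions = pca_r$variance_fractions[1:3],
    displaced_residues = disp$exceeding,
    rotamer_runs = if (!is.null(rot)) rot$runs else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_msg("pipeline: reports written to %s", config$out_dir)
  invisible(list(structure = s, sphere = sphere, tau = tau, jahn_teller = jt,
                 tau_series = taus, rmsd = rmsd_r, rmsf = rmsf_r,
                 bfactor = bf, pca = pca_r, displacement = disp,
                 rotamers = rot))
}

read_config <- function(path) {
  if (grepl("\\.json$", path)) return(jsonlite::read_json(path, simplifyVector = TRUE))
  if (requireNamespace("yaml", quietly = TRUE)) return(yaml::read_yaml(path))
  stop("cannot read config ", path)
}

validate_config <- function(config) {
  defaults <- list(input_pdb = NULL, n_frames = 180, sigma = 0.3,
                   cutoff = 2.6, displacement_threshold = 3, min_run = 5,
                   frame_spacing_ps = 40,
                   rotamer_schedule = data.frame(
                     code = c("pttp", "mtmt", "pttp"),
                     length = c(80, 60, 40)))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
      if (!is.null(defaults[[nm]]) && !is.data.frame(defaults[[nm]]))
        message(sprintf("config: using default %s = %s", nm,
                        paste(defaults[[nm]], collapse = ",")))
    }
  }
  if (is.null(config$seed)) stop("config: `seed` is required")
  if (is.null(config$out_dir)) stop("config: `out_dir` is required")
  if (!is.numeric(config$cutoff) || config$cutoff <= 0 || config$cutoff > 5)
    stop("config: cutoff must be in (0, 5] angstrom")
  if (config$n_frames < 2) stop("config: n_frames must be >= 2")
  if (config$sigma < 0) stop("config: sigma must be >= 0")
  if (config$min_run < 1) stop("config: min_run must be >= 1")
  if (config$displacement_threshold < 0)
    stop("config: displacement_threshold must be >= 0")
  if (is.list(config$rotamer_schedule) && !is.data.frame(config$rotamer_schedule))
    config$rotamer_schedule <- as.data.frame(config$rotamer_schedule)
  config$seed <- as.integer(config$seed)
  config
}
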
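#' Configuration for a full pipeline run
#'
#' Holds either paths to the five input files or a simulation
#' configuration (exactly one of the two), plus every stage parameter.
#'
#' @param input_paths named list/vector with entries `community`,
#'   `traits`, `tree`, `sites`, `status`, or `NULL` to simulate.
#' @param sim a `rip_sim_config`, or `NULL` when `input_paths` is given.
#' @param n_reps null-model replicates (default 1000).
#' @param n_perm signal-test permutations (default 999).
#' @param shannon_base Shannon log base (default 2).
#' @param cvi_base CVI log base (default 10).
#' @param min_sites occurrence filter threshold (default 3).
#' @param vif_threshold stepwise VIF threshold (default 4).
#' @param delta_aicc top-set cutoff (default 2).
#' @param k spline basis dimension (default 5).
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for [run_full_analysis()].
#' @return an object of class `rip_pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, sim = NULL,
                            n_reps = 1000, n_perm = 999,
                            shannon_base = 2, cvi_base = 10,
                            min_sites = 3, vif_threshold = 4,
                            delta_aicc = 2, k = 5, seed = 1,
                            out_dir = tempfile("ripdiv_run_")) {
  if (is.null(input_paths) && is.null(sim)) sim <- sim_config(seed = seed)
  if (!is.null(input_paths) && !is.null(sim))
    rip_stop("give either input_paths or sim, not both")
  for (arg in c("n_reps", "n_perm", "min_sites", "k")) {
    v <- get(arg)
    if (!is.numeric(v) || v < 1)
      rip_stop("'", arg, "' must be a positive count")
  }
  if (n_reps < 2) rip_stop("'n_reps' must be >= 2")
  structure(list(input_paths = input_paths, sim = sim, n_reps = n_reps,
                 n_perm = n_perm, shannon_base = shannon_base,
                 cvi_base = cvi_base, min_sites = min_sites,
                 vif_threshold = vif_threshold, delta_aicc = delta_aicc,
                 k = k, seed = seed, out_dir = out_dir),
            class = "rip_pipeline_config")
}

#' Run the complete analysis pipeline
#'
#' Loads (or simulates) a dataset, applies the low-occurrence filter,
#' and runs every stage: the diversity profile (S, H', FRic, PD), the
#' richness-null SES of FRic and PD, per-trait phylogenetic signal, the
#' conservation value index, elevation smooths of the four diversity
#' responses, the CVI--elevation polynomial GLM, and driver inference
#' for S, H', sesFD and sesPD. All result tables are written as CSV to
#' `config$out_dir` together with a JSON run manifest.
#'
#' @param config a `rip_pipeline_config`.
#' @return (invisibly) a list with elements `profile`, `signal`,
#'   `decoupling`, `smooths`, `peaks`, `cvi_glm`, `drivers`, `dataset`,
#'   `files`.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      rip_stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    list(value = res, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  timings <- list()
  run <- function(name, expr) {
    s <- stage(name, expr)
    timings[[name]] <<- round(s$secs, 3)
    s$value
  }

  ds <- run("load", {
    if (!is.null(config$input_paths)) {
      p <- config$input_paths
      load_dataset(p[["community"]], p[["traits"]], p[["tree"]],
                   p[["sites"]], p[["status"]])
    } else generate_study(config$sim)
  })
  ds$community <- run("filter", filter_low_occurrence(ds$community,
                                                      config$min_sites))
  ds <- run("reconcile", rip_dataset(ds$community, ds$traits, ds$tree,
                                     ds$sites, ds$status))

  profile <- run("diversity", diversity_profile(ds, shannon_base = config$shannon_base))
  space <- attr(profile, "trait_space")
  ses <- run("ses", suppressWarnings(
    ses_profile(ds$community, ds$tree, space, n_reps = config$n_reps,
                seed = rip_substream(config$seed, "null"))))
  profile$sesFD <- ses$sesFD
  profile$sesPD <- ses$sesPD
  profile$CVI <- run("cvi", as.numeric(
    cvi_profile(ds$community, ds$status, log_base = config$cvi_base)))

  signal <- run("signal", signal_profile(ds$traits, ds$tree,
                                         n_perm = config$n_perm,
                                         seed = rip_substream(config$seed, "perm")))
  decoupling <- run("decoupling", richness_decoupling_check(profile))

  responses <- c(S = "S", Shannon = "H", FRic = "FRic", PD = "PD")
  smooths <- run("gradient", {
    lapply(names(responses), function(nm) {
      y <- stats::setNames(profile[[responses[[nm]]]], profile$site)
      suppressWarnings(fit_elevation_smooth(y, ds$sites, k = config$k,
                                            response_name = nm))
    })
  })
  names(smooths) <- names(responses)
  peaks <- lapply(smooths, peak_location)
  cvi_glm <- run("cvi_glm", fit_cvi_glm(
    stats::setNames(profile$CVI, profile$site), ds$sites))

  driver_responses <- c(S = "S", Shannon = "H", sesFD = "sesFD", sesPD = "sesPD")
  drivers <- run("drivers", {
    lapply(names(driver_responses), function(nm) {
      y <- stats::setNames(profile[[driver_responses[[nm]]]], profile$site)
      suppressWarnings(infer_drivers(y, ds$sites,
                                     vif_threshold = config$vif_threshold,
                                     delta = config$delta_aicc))
    })
  })
  names(drivers) <- names(driver_responses)

  # ---- write the result bundle -----------------------------------------
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  files <- character()
  wcsv <- function(x, name, row.names = FALSE) {
    utils::write.csv(x, out(name), row.names = row.names)
    files <<- c(files, out(name))
  }
  wcsv(profile, "diversity_profile.csv")
  wcsv(signal, "phylo_signal.csv")
  wcsv(decoupling, "richness_decoupling.csv")
  for (nm in names(smooths))
    wcsv(smooths[[nm]]$grid, paste0("smooth_", nm, ".csv"))
  wcsv(cvi_glm$grid, "cvi_glm_curve.csv")
  driver_tab <- do.call(rbind, lapply(names(drivers), function(nm)
    cbind(response = nm, drivers[[nm]]$averaged)))
  wcsv(driver_tab, "driver_table.csv")
  vif_log <- do.call(rbind, lapply(names(drivers), function(nm) {
    rem <- drivers[[nm]]$vif_removed
    if (nrow(rem)) cbind(response = nm, rem) else NULL
  }))
  wcsv(vif_log %||% data.frame(response = character(), predictor = character(),
                               vif = numeric()), "vif_removals.csv")

  manifest <- list(
    seed = config$seed,
    n_reps = config$n_reps, n_perm = config$n_perm,
    shannon_base = config$shannon_base, cvi_base = config$cvi_base,
    min_sites = config$min_sites, vif_threshold = config$vif_threshold,
    delta_aicc = config$delta_aicc, k = config$k,
    n_sites = nrow(ds$community), n_species = ncol(ds$community),
    peaks = lapply(peaks, function(p) p[c("elevation", "classification")]),
    stage_seconds = timings,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ripdiv")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, out("manifest.json"))

  invisible(list(profile = profile, signal = signal, decoupling = decoupling,
                 smooths = smooths, peaks = peaks, cvi_glm = cvi_glm,
                 drivers = drivers, dataset = ds, files = files))
}
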
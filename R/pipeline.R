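#' Experiment configuration
#'
#' Describes one full noise-robustness experiment: a phantom, a set of noise
#' levels (HU), the processing branches to compare against the noiseless
#' reference (`"noise"` = no denoising, `"median"` = 3 x 3 median filter,
#' `"cnn"` = U-Net denoiser), a registration configuration, and either a
#' trained denoiser or the training settings to fit one on the phantom's
#' clean slices.
#'
#' @param phantom a [phantom_spec()].
#' @param noise_levels Gaussian noise SDs in HU (>= 0).
#' @param branches non-empty subset of `c("noise", "median", "cnn")`.
#' @param registration a [reg_config()].
#' @param denoiser optional trained `unet_denoiser`; required by the cnn
#'   branch unless `train` + `unet` are supplied.
#' @param train a [train_config()] used to train the denoiser when none is
#'   given.
#' @param unet a [unet_spec()] matching the phantom's in-plane size.
#' @param bins 2-D histogram bins.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for volumes, maps and reports.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              noise_levels = study_noise_levels(),
                              branches = c("noise", "median", "cnn"),
                              registration = reg_config(),
                              denoiser = NULL,
                              train = NULL,
                              unet = NULL,
                              bins = 100L,
                              seed = 0L,
                              out_dir = NULL) {
  if (!length(branches))
    stop("at least one processing branch is required", call. = FALSE)
  known <- c("noise", "median", "cnn")
  if (!all(branches %in% known))
    stop("unknown branch(es): ", paste(setdiff(branches, known),
                                       collapse = ", "),
         "; branches must be a subset of noise/median/cnn", call. = FALSE)
  if (!length(noise_levels) || any(noise_levels < 0))
    stop("noise_levels must be non-negative HU values", call. = FALSE)
  if ("cnn" %in% branches && is.null(denoiser) &&
      (is.null(train) || is.null(unet)))
    stop("the cnn branch needs a trained `denoiser` or `train` + `unet` to ",
         "fit one", call. = FALSE)
  structure(list(phantom = phantom, noise_levels = as.numeric(noise_levels),
                 branches = branches, registration = registration,
                 denoiser = denoiser, train = train, unet = unet,
                 bins = as.integer(bins), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Desk-scale experiment configuration
#'
#' The scaled-down experiment profile used throughout the package's tests and
#' vignette: the default 96 x 96 x 48 phantom, the three study noise levels,
#' all three branches, a two-step SSD-driven registration cascade with three
#' pyramid levels, and a small U-Net (8 base filters on 96 x 96 slices)
#' trained briefly on the phantom's clean slices.
#'
#' @param seed master seed.
#' @param noise_levels noise SDs in HU.
#' @param epochs denoiser training epochs.
#' @return An [experiment_config()].
#' @export
desk_experiment_config <- function(seed = 1L,
                                   noise_levels = study_noise_levels(),
                                   epochs = 20L) {
  experiment_config(
    phantom = phantom_spec(seed = seed),
    noise_levels = noise_levels,
    branches = c("noise", "median", "cnn"),
    registration = reg_config(n_steps = 2L, levels = 3L, max_iterations = 40L,
                              similarity = "ssd", bending_weight = 1,
                              jacobian_weight = 0.05, seed = seed),
    train = train_config(max_epochs = epochs, crop_size = 48L,
                         learning_rate = 1e-3, val_slices_per_sigma = 4L,
                         seed = seed),
    unet = unet_spec(depth = 3L, base_filters = 8L, input_size = 96L),
    bins = 64L,
    seed = seed)
}

branch_process <- function(branch, image, model) {
  switch(branch,
         noise = image,
         median = median_filter(image),
         cnn = denoise_cnn(model, image),
         stop("unknown branch: ", branch, call. = FALSE))
}

#' Run the full noise-robustness experiment
#'
#' Generates one phantom realization, registers the clean pair to obtain the
#' reference ventilation map CTVI_ref and its category thresholds, then for
#' every noise level and branch: adds independent Gaussian noise to exhale
#' and inhale, applies the branch's denoiser, registers the processed pair,
#' derives the Jacobian ventilation map over the foam mask, classifies it
#' with the *reference* thresholds, and evaluates TRE, category agreement,
#' Cohen's kappa, the 2-D histogram and Spearman rho against CTVI_ref. The
#' run is fully determined by the configuration (including its seed).
#'
#' @param cfg an [experiment_config()].
#' @return An object of class `ctvi_experiment`: list with `phantom`,
#'   `reference` (dvf, ctvi, tre, thresholds), `results` (one entry per
#'   branch x sigma with dvf, ctvi, report, tre), `denoiser`, `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  phantom <- generate_phantom(cfg$phantom)
  mask <- phantom$foam_mask

  model <- cfg$denoiser
  if ("cnn" %in% cfg$branches && is.null(model)) {
    clean <- c(lapply(seq_len(dim(phantom$exhale$data)[3]),
                      function(k) phantom$exhale$data[, , k]),
               lapply(seq_len(dim(phantom$inhale$data)[3]),
                      function(k) phantom$inhale$data[, , k]))
    model <- train_denoiser(clean, cfg$train, cfg$unet)
  }

  dvf_ref <- register_ffd(phantom$exhale, phantom$inhale, cfg$registration)
  ctvi_ref <- jacobian_map(dvf_ref, mask)
  thresholds <- tertile_thresholds(ctvi_ref)
  tre_ref <- target_registration_error(phantom$landmarks_exhale,
                                       phantom$landmarks_inhale, dvf_ref)

  results <- list()
  for (sigma in cfg$noise_levels) {
    noisy_ex <- add_gaussian_noise(phantom$exhale, sigma,
                                   seed = derive_seed(cfg$seed, "exhale", sigma))
    noisy_in <- add_gaussian_noise(phantom$inhale, sigma,
                                   seed = derive_seed(cfg$seed, "inhale", sigma))
    for (branch in cfg$branches) {
      key <- sprintf("%s_%g", branch, sigma)
      res <- tryCatch({
        proc_ex <- branch_process(branch, noisy_ex, model)
        proc_in <- branch_process(branch, noisy_in, model)
        dvf <- register_ffd(proc_ex, proc_in, cfg$registration)
        ctvi <- jacobian_map(dvf, mask)
        report <- consistency_report(ctvi_ref, ctvi, thresholds,
                                     bins = cfg$bins)
        tre <- target_registration_error(phantom$landmarks_exhale,
                                         phantom$landmarks_inhale, dvf)
        list(branch = branch, sigma = sigma, dvf = dvf, ctvi = ctvi,
             report = report, tre = tre)
      }, error = function(e) {
        stop(sprintf("branch '%s' at sigma %g HU failed: %s", branch, sigma,
                     conditionMessage(e)), call. = FALSE)
      })
      results[[key]] <- res
    }
  }

  out <- structure(list(phantom = phantom,
                        reference = list(dvf = dvf_ref, ctvi = ctvi_ref,
                                         thresholds = thresholds,
                                         tre = tre_ref),
                        results = results, denoiser = model, config = cfg),
                   class = "ctvi_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

#' Summary tables of an experiment
#'
#' Produces the comparative tables of the study design: kappa and Spearman
#' rho per method and noise level (with p-values), a TRE table
#' (mean, SD, max in mm) including the reference row, and a long table of the
#' 3 x 3 agreement proportions.
#'
#' @param experiment a `ctvi_experiment` from [run_experiment()].
#' @return List of data.frames `kappa`, `rho`, `tre`, `confusion`.
#' @export
summarize_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "ctvi_experiment"))
  res <- experiment$results
  if (!length(res)) stop("experiment has no results to summarize",
                         call. = FALSE)
  rows <- lapply(res, function(r) data.frame(
    method = r$branch, sigma_hu = r$sigma, kappa = r$report$kappa,
    kappa_p = r$report$kappa_p, rho = r$report$rho, rho_p = r$report$rho_p,
    agreement = sum(diag(r$report$confusion))))
  stat <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  kappa_tab <- stat[, c("method", "sigma_hu", "kappa", "kappa_p", "agreement")]
  rho_tab <- stat[, c("method", "sigma_hu", "rho", "rho_p")]
  tre_rows <- c(list(data.frame(method = "reference", sigma_hu = 0,
                                tre_mean = experiment$reference$tre$mean,
                                tre_sd = experiment$reference$tre$sd,
                                tre_max = experiment$reference$tre$max)),
                lapply(res, function(r) data.frame(
                  method = r$branch, sigma_hu = r$sigma,
                  tre_mean = r$tre$mean, tre_sd = r$tre$sd,
                  tre_max = r$tre$max)))
  tre_tab <- do.call(rbind, c(tre_rows, list(make.row.names = FALSE)))
  conf_rows <- lapply(res, function(r) {
    cf <- r$report$confusion
    data.frame(method = r$branch, sigma_hu = r$sigma,
               reference = rep(rownames(cf), times = ncol(cf)),
               test = rep(colnames(cf), each = nrow(cf)),
               proportion = as.vector(cf))
  })
  conf_tab <- do.call(rbind, c(conf_rows, list(make.row.names = FALSE)))
  list(kappa = kappa_tab, rho = rho_tab, tre = tre_tab, confusion = conf_tab)
}

#' @export
print.ctvi_experiment <- function(x, ...) {
  s <- summarize_experiment(x)
  cat(sprintf("<ctvi_experiment> %d evaluated CTVIs + reference\n",
              length(x$results)))
  print(s$kappa, row.names = FALSE)
  invisible(x)
}

#' Persist an experiment to disk
#'
#' Writes phantom volumes, every branch's displacement field and ventilation
#' map (NIfTI), the summary tables (CSV), and a manifest (JSON) capturing the
#' configuration and seeds.
#'
#' @param experiment a `ctvi_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phantom(experiment$phantom, file.path(dir, "phantom"))
  sp <- experiment$phantom$exhale$spacing
  write_volume(experiment$reference$dvf, file.path(dir, "dvf_ref.nii.gz"))
  write_volume(ct_volume(experiment$reference$ctvi$values, sp),
               file.path(dir, "ctvi_ref.nii.gz"))
  for (key in names(experiment$results)) {
    r <- experiment$results[[key]]
    write_volume(r$dvf, file.path(dir, sprintf("dvf_%s.nii.gz", key)))
    write_volume(ct_volume(r$ctvi$values, sp),
                 file.path(dir, sprintf("ctvi_%s.nii.gz", key)))
  }
  s <- summarize_experiment(experiment)
  for (nm in names(s))
    utils::write.csv(s[[nm]], file.path(dir, sprintf("%s.csv", nm)),
                     row.names = FALSE)
  cfg <- experiment$config
  manifest <- list(
    seed = cfg$seed,
    noise_levels = cfg$noise_levels,
    branches = cfg$branches,
    phantom = unclass(cfg$phantom),
    registration = unclass(cfg$registration),
    thresholds = experiment$reference$thresholds,
    format_versions = list(nifti = "NIfTI-1", landmarks_csv = "id,x_mm,y_mm,z_mm"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [experiment_config()] (`phantom`, `registration`, `train`, `unet` given as
#' key-value maps of the respective constructor arguments).
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$registration))
    args$registration <- do.call(reg_config, y$registration)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$unet)) args$unet <- do.call(unet_spec, y$unet)
  for (nm in c("noise_levels", "branches", "bins", "seed", "out_dir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(experiment_config, args)
}
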
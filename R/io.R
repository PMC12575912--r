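# Readers and writers for the pipeline's on-disk formats: the cohort CSV
# dialect (comma separator, dot decimal, header row), signal-curve CSVs,
# NIfTI-1 volumes, and the YAML run configuration.

#' Write / read a cohort table
#'
#' The cohort CSV dialect has one row per subject x reader and exactly the
#' columns `subject_id, lvi, reader, mk, md, suvmax, mtv, tlg, adc, d,
#' dstar, f_pct`, with `lvi` coded `"+"` / `"-"`.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  write.csv(cohort[, c("subject_id", "lvi", "reader", BIOMARKERS)], path,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_cohort(tibble::as_tibble(df))
}

#' Write / read diffusion signal curves
#'
#' Curves are stored as a CSV with a `b` column (s/mm2) followed by one
#' column per curve.
#'
#' @param b B-value scheme.
#' @param signals Numeric matrix (rows = b-values) or vector of one curve.
#' @param path File path.
#' @return `write_curves` returns `path` invisibly; `read_curves` returns a
#'   list with `b` and the signal matrix `signals`.
#' @export
write_curves <- function(b, signals, path) {
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) == length(b))
  if (is.null(colnames(signals))) {
    colnames(signals) <- sprintf("curve%03d", seq_len(ncol(signals)))
  }
  write.csv(cbind(data.frame(b = b), as.data.frame(signals)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "b") stop("first column must be b", call. = FALSE)
  list(b = df$b, signals = as.matrix(df[, -1, drop = FALSE]))
}

#' Write / read a PET volume as NIfTI-1
#'
#' The voxel spacing travels in the NIfTI pixdim field; everything else
#' uses RNifti defaults.
#'
#' @param volume A `pet_volume`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_pet_volume` returns `path` invisibly; `read_pet_volume`
#'   a `pet_volume`.
#' @export
write_pet_volume <- function(volume, path) {
  vol <- as_pet_volume(volume)
  img <- RNifti::asNifti(vol$suv)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @export
read_pet_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(suv = array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3]),
            class = "pet_volume")
}

#' Write / read a run configuration
#'
#' Serializes a [`cohort_config`] (plus optional extra scalar settings such
#' as the noise SNR) to a flat YAML file and restores it, rebuilding the
#' `biomarker_dist` calibration objects.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @param extra Optional named list of additional scalar settings.
#' @return `write_config` returns `path` invisibly; `read_config` a list
#'   with `config` (the `cohort_config`) and `extra`.
#' @export
write_config <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "cohort_config"))
  cal <- lapply(BIOMARKERS, function(bm) {
    lapply(stats::setNames(c("pos", "neg"), c("pos", "neg")), function(g) {
      d <- config$calibration[[bm]][[g]]
      if (d$family == "lognormal") {
        list(family = "lognormal", center = d$center, lower = d$lower,
             upper = d$upper, spread = d$spread,
             n = if (g == "pos") config$n_pos else config$n_neg)
      } else {
        list(family = "normal_trunc0", mean = d$mean, sd = d$sd)
      }
    })
  })
  names(cal) <- BIOMARKERS
  yaml::write_yaml(list(
    n_pos = config$n_pos, n_neg = config$n_neg, icc = config$icc,
    seed = config$seed, calibration = cal, extra = extra
  ), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed config ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  for (key in c("n_pos", "n_neg", "icc", "calibration")) {
    if (is.null(raw[[key]])) stop("config is missing key: ", key, call. = FALSE)
  }
  cal <- lapply(BIOMARKERS, function(bm) {
    entry <- raw$calibration[[bm]]
    if (is.null(entry)) stop("config is missing calibration for ", bm, call. = FALSE)
    lapply(stats::setNames(c("pos", "neg"), c("pos", "neg")), function(g) {
      d <- entry[[g]]
      if (identical(d$family, "lognormal")) {
        calibrate_quantiles(d$center, d$lower, d$upper,
                            spread = d$spread, n = d$n)
      } else {
        normal_dist(d$mean, d$sd)
      }
    })
  })
  names(cal) <- BIOMARKERS
  list(
    config = cohort_config(raw$n_pos, raw$n_neg, icc = raw$icc,
                           calibration = cal, seed = raw$seed),
    extra = raw$extra %||% list()
  )
}

#' Write the study report tables
#'
#' Emits the report of [run_pipeline()] as one CSV per table plus a
#' plain-text summary.
#'
#' @param report An `lvi_study_report`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = "report") {
  stopifnot(inherits(report, "lvi_study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(icc = report$icc, comparison = report$comparison,
                 univariate = report$univariate,
                 multivariate = report$multivariate,
                 roc_parameters = report$roc_parameters,
                 roc_combinations = report$roc_combinations)
  paths <- character()
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sum_path <- file.path(dir, sprintf("%s_summary.txt", prefix))
  con <- file(sum_path, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(c(paths, sum_path))
}
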
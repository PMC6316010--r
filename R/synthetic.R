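# Synthetic two-instrument cohorts.
#
# The generator states the world the analysis assumes and nothing more:
# class-dependent analyte amplitudes, an exponential storage-age decay of
# analyte signal, and i.i.d. additive Gaussian measurement noise. FAIMS
# maps carry a drifting reactive-ion peak (RIP) plus Gaussian analyte
# peaks at fixed (CV, DF) loci; eNose traces follow first-order exposure
# kinetics R(t) = R0 - A (1 - exp(-t/tau)) with sensor-specific (A, tau).
# No sensor drift, humidity or chemically realistic spectra are modelled.

#' Configuration of a synthetic cohort
#'
#' @param n_case,n_control cohort sizes (defaults mirror a 73 case / 67
#'   control clinical cohort).
#' @param seed RNG seed; identical seed and config give bit-identical
#'   cohorts.
#' @param n_marker_peaks number of FAIMS analyte peaks whose amplitude
#'   differs by class.
#' @param effect_size multiplier (> 0) on marker amplitude for cases;
#'   1 means no class effect.
#' @param noise_sd additive Gaussian noise standard deviation (ion-current
#'   units for FAIMS, resistance units for eNose). The default of 2 places
#'   the detection floor above a 10x-decayed unit-amplitude analyte peak:
#'   samples stored long enough to lose ~90% of their volatile signal are
#'   no longer diagnosable, while fresh class effects remain separable.
#' @param age_decay_rate per-day exponential decay constant lambda (>= 0)
#'   applied to analyte/marker amplitude as `exp(-lambda * age_days)`.
#' @param age_distribution either `list(min =, max =)` for uniform sampling
#'   of ages in days, or a numeric vector of explicit ages (recycled over
#'   the cohort). Default: uniform on 0-4 years.
#' @param n_marker_sensors number of eNose sensors with class-dependent
#'   response amplitude.
#' @param enose_amplitude scalar multiplier on every sensor's response
#'   amplitude (0 gives flat traces at baseline).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 73L, n_control = 67L, seed = 1L,
                             n_marker_peaks = 4L, effect_size = 2,
                             noise_sd = 2, age_decay_rate = 0,
                             age_distribution = list(min = 0, max = 1460),
                             n_marker_sensors = 3L, enose_amplitude = 1) {
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  if (is.na(n_case) || is.na(n_control) || n_case < 0L || n_control < 0L)
    stop("n_case and n_control must be non-negative counts")
  if (!is.finite(effect_size) || effect_size <= 0)
    stop("effect_size must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0")
  if (!is.finite(age_decay_rate) || age_decay_rate < 0)
    stop("age_decay_rate must be >= 0")
  if (is.list(age_distribution)) {
    stopifnot(all(c("min", "max") %in% names(age_distribution)),
              age_distribution$min >= 0,
              age_distribution$max >= age_distribution$min)
  } else {
    stopifnot(is.numeric(age_distribution), all(age_distribution >= 0))
  }
  structure(list(n_case = n_case, n_control = n_control,
                 seed = as.integer(seed),
                 n_marker_peaks = as.integer(n_marker_peaks),
                 effect_size = effect_size, noise_sd = noise_sd,
                 age_decay_rate = age_decay_rate,
                 age_distribution = age_distribution,
                 n_marker_sensors = as.integer(n_marker_sensors),
                 enose_amplitude = enose_amplitude),
            class = "synthetic_config")
}

cohort_labels <- function(config) {
  c(rep("case", config$n_case), rep("control", config$n_control))
}

draw_age <- function(config, i, n_total) {
  ad <- config$age_distribution
  if (is.list(ad)) {
    runif(1L, ad$min, ad$max)
  } else {
    ad[((i - 1L) %% length(ad)) + 1L]
  }
}

# Fixed analyte-peak loci (CV step, DF step) in the positive-polarity
# block. Marker peaks sit clear of the RIP trajectory; common peaks are
# shared by both classes and carry the same age decay.
faims_marker_loci <- function(n) {
  if (n == 0L) return(cbind(cv = integer(), df = integer()))
  cbind(cv = round(seq(300, 460, length.out = n)),
        df = round(seq(12, 40, length.out = n)))
}

faims_common_loci <- function() {
  cbind(cv = c(150, 190, 220), df = c(20, 30, 38))
}

# Additive 2D Gaussian peak on one polarity block of a FAIMS matrix.
add_faims_peak <- function(m, col_offset, cv0, df0, amp,
                           sigma_cv = 5, sigma_df = 3) {
  cv <- seq_len(nrow(m))
  df <- seq_len(FAIMS_DF_STEPS)
  peak <- amp * outer(exp(-0.5 * ((cv - cv0) / sigma_cv)^2),
                      exp(-0.5 * ((df - df0) / sigma_df)^2))
  m[, col_offset + df] <- m[, col_offset + df] + peak
  m
}

faims_background <- function() {
  # reactive-ion peak: Gaussian in CV whose position drifts linearly with
  # the dispersion-field index and whose intensity decays as analytes
  # fragment at high fields; weaker mirror in the negative-ion block
  m <- matrix(0, FAIMS_CV_STEPS, FAIMS_COLS)
  cv <- seq_len(FAIMS_CV_STEPS)
  for (d in seq_len(FAIMS_DF_STEPS)) {
    center <- 256 - 3 * (d - 1L)
    shape <- exp(-0.5 * ((cv - center) / 6)^2)
    m[, d] <- m[, d] + 10 * exp(-(d - 1L) / 40) * shape
    m[, FAIMS_DF_STEPS + d] <- m[, FAIMS_DF_STEPS + d] +
      5 * exp(-(d - 1L) / 40) * shape
  }
  m
}

#' Generate a synthetic FAIMS cohort
#'
#' Each sample is a 512 x 102 ion-current matrix (52,224 values): a
#' drifting reactive-ion peak in both polarity blocks, three
#' class-independent analyte peaks, `n_marker_peaks` marker peaks whose
#' amplitude is `effect_size`-fold higher in cases, and i.i.d. Gaussian
#' noise. All analyte amplitudes (marker and common, but not the RIP) are
#' scaled by `exp(-age_decay_rate * age_days)`. Cases are generated first,
#' then controls.
#'
#' The effective marker amplitude of each sample is attached as attribute
#' `"marker_amplitude"` for auditing the planted signal.
#'
#' @param config a [synthetic_config()].
#' @return List of [faims_sample()] objects of length
#'   `n_case + n_control`.
#' @export
generate_faims_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- cohort_labels(config)
  n <- length(labels)
  bg <- faims_background()
  markers <- faims_marker_loci(config$n_marker_peaks)
  common <- faims_common_loci()
  with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      age <- draw_age(config, i, n)
      decay <- exp(-config$age_decay_rate * age)
      amp <- decay * if (labels[i] == "case") config$effect_size else 1
      m <- bg
      for (k in seq_len(nrow(common)))
        m <- add_faims_peak(m, 0L, common[k, "cv"], common[k, "df"], decay)
      for (k in seq_len(nrow(markers)))
        m <- add_faims_peak(m, 0L, markers[k, "cv"], markers[k, "df"], amp)
      if (config$noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, config$noise_sd),
                        nrow(m), ncol(m))
      s <- faims_sample(m, sprintf("S%03d", i), label = labels[i],
                        age_days = age)
      attr(s, "marker_amplitude") <- amp
      s
    })
  })
}

# Deterministic per-sensor kinetics; marker sensors are spread across the
# array.
enose_sensor_params <- function() {
  s <- seq_len(ENOSE_N_SENSORS)
  list(r0 = 100 + 8 * s, a = 12 + 1.5 * s, tau = 8 + 2 * s)
}

marker_sensor_indices <- function(n) {
  if (n == 0L) return(integer())
  unique(round(seq(1, ENOSE_N_SENSORS, length.out = n + 2L)))[seq_len(n) + 1L]
}

#' Generate a synthetic electronic-nose cohort
#'
#' Each of the 18 sensor traces follows first-order exposure kinetics
#' `R(t) = R0 - A (1 - exp(-t / tau))` over 180 s at 1 Hz, with
#' sensor-specific `(R0, A, tau)`. For `n_marker_sensors` sensors the
#' response amplitude `A` is multiplied by `effect_size` in cases; for all
#' sensors it is multiplied by `exp(-age_decay_rate * age_days)`. Gaussian
#' noise of sd `noise_sd` is added to every point.
#'
#' The effective marker-sensor amplitudes are attached as attribute
#' `"marker_amplitude"`.
#'
#' @param config a [synthetic_config()].
#' @return List of [enose_sample()] objects.
#' @export
generate_enose_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- cohort_labels(config)
  n <- length(labels)
  par <- enose_sensor_params()
  mk <- marker_sensor_indices(config$n_marker_sensors)
  tt <- 0:(ENOSE_N_POINTS - 1L)
  with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      age <- draw_age(config, i, n)
      decay <- exp(-config$age_decay_rate * age)
      a_eff <- par$a * config$enose_amplitude * decay
      if (labels[i] == "case") a_eff[mk] <- a_eff[mk] * config$effect_size
      traces <- t(vapply(seq_len(ENOSE_N_SENSORS), function(s)
        par$r0[s] - a_eff[s] * (1 - exp(-tt / par$tau[s])),
        numeric(ENOSE_N_POINTS)))
      if (config$noise_sd > 0)
        traces <- traces + matrix(rnorm(length(traces), 0, config$noise_sd),
                                  nrow(traces), ncol(traces))
      s <- enose_sample(traces, sprintf("S%03d", i), baselines = par$r0,
                        label = labels[i], age_days = age)
      attr(s, "marker_amplitude") <- a_eff[mk]
      s
    })
  })
}

#' Write a cohort to disk
#'
#' Writes one file per sample in the format its reader consumes
#' ([read_faims_sample()] / [read_enose_sample()]) plus a `metadata.csv`
#' with columns `sample_id,label,age_days,replicate_index`.
#'
#' @param cohort list of [faims_sample()] or [enose_sample()] objects.
#' @param dir output directory (created if needed).
#' @param dialect FAIMS output dialect.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "plain_csv") {
  stopifnot(length(cohort) > 0L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_faims <- inherits(cohort[[1L]], "faims_sample")
  meta <- data.frame(
    sample_id = vapply(cohort, `[[`, character(1L), "sample_id"),
    label = vapply(cohort, `[[`, character(1L), "label"),
    age_days = vapply(cohort, `[[`, numeric(1L), "age_days"),
    replicate_index = vapply(cohort, function(s)
      s$replicate_index %||% 1L, integer(1L)))
  for (s in cohort) {
    f <- file.path(dir, paste0(s$sample_id, ".csv"))
    if (is_faims) write_faims_sample(s, f, dialect = dialect)
    else write_enose_sample(s, f)
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `metadata.csv`.
#' @param instrument `"faims"` or `"enose"`.
#' @param dialect FAIMS input dialect.
#' @return List of sample objects in metadata order.
#' @export
read_cohort <- function(dir, instrument = c("faims", "enose"),
                        dialect = "plain_csv") {
  instrument <- match.arg(instrument)
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir)
  meta <- utils::read.csv(meta_path)
  has_rep <- "replicate_index" %in% names(meta)
  lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, paste0(meta$sample_id[i], ".csv"))
    if (instrument == "faims") {
      read_faims_sample(f, dialect = dialect, sample_id = meta$sample_id[i],
                        label = meta$label[i], age_days = meta$age_days[i],
                        replicate_index = if (has_rep) meta$replicate_index[i] else 1L)
    } else {
      read_enose_sample(f, sample_id = meta$sample_id[i],
                        label = meta$label[i], age_days = meta$age_days[i])
    }
  })
}
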
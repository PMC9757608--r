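#' Configuration for the synthetic serum-panel generator
#'
#' Collects the study-design constants and distributional parameters of the
#' synthetic sample-by-marker generator. Defaults reproduce the design of a
#' two-stage autoantibody panel study: a training set of 332 early-stage
#' cancer sera against 167 benign and 208 normal controls, an independent
#' test set of 163 cases against 183 benign controls, 36 measured
#' autoantibody markers of which 12 carry signal, and a core panel of 8
#' markers carrying the strongest signal. Four conventional serum tumor
#' markers (CYFRA21-1, CEA, SCCA, NSE) carry weaker, independent signal.
#'
#' Marker abundances are log-normal: Gaussian on the log scale (location
#' `log_mean_baseline`, spread `log_sd`), exponentiated, so values are
#' strictly positive and right-skewed like bead-array fluorescence
#' intensities. Tumor heterogeneity is modelled as per-(case, marker)
#' Bernoulli positivity: a case elevates a given informative marker with
#' probability `positivity_rate`, and only then is the log-scale effect
#' added. The informative markers outside the core panel share their
#' positivity events with a paired core marker (cross-reactive antigens) and
#' carry the smaller effect `effect_log_weak`, so they are statistically
#' significant yet largely redundant once the core panel is in a model.
#'
#' @param n_case_train,n_benign_train,n_normal_train training-set group sizes.
#' @param n_case_test,n_benign_test test-set group sizes.
#' @param n_markers number of autoantibody markers measured.
#' @param n_informative number of markers carrying any signal.
#' @param panel_true indices (within the informative set) of the core panel
#'   markers carrying the strongest signal.
#' @param positivity_rate probability in \[0,1\] that a given case elevates a
#'   given informative marker.
#' @param log_mean_baseline log-scale location of background abundance
#'   (arbitrary fluorescence units).
#' @param log_sd log-scale standard deviation (> 0).
#' @param effect_log log-scale shift added when a case is positive for a
#'   core-panel marker.
#' @param effect_log_weak log-scale shift for informative non-core markers.
#' @param cross_reactive_weak if `TRUE` (default), informative non-core
#'   markers share positivity events with a paired core marker.
#' @param serum_marker_effect log-scale shift for the 4 serum tumor markers
#'   when a case is serum-positive (>= 0).
#' @param serum_positivity_rate probability a case elevates a given serum
#'   marker (independent of autoantibody positivity).
#' @param benign_shift optional log-scale shift applied to all markers in
#'   benign controls (mild inflammation); default 0 (off).
#' @param seed integer seed driving the single pseudo-random stream.
#' @return an object of class `panel_sim_config` (a validated list).
#' @seealso [simulate_panel_data()]
#' @export
panel_sim_config <- function(n_case_train = 332, n_benign_train = 167,
                             n_normal_train = 208, n_case_test = 163,
                             n_benign_test = 183, n_markers = 36,
                             n_informative = 12, panel_true = 1:8,
                             positivity_rate = 0.35,
                             log_mean_baseline = log(500), log_sd = 1,
                             effect_log = 2.5, effect_log_weak = 0.5,
                             cross_reactive_weak = TRUE,
                             serum_marker_effect = 1.0,
                             serum_positivity_rate = 0.5,
                             benign_shift = 0, seed = 1) {
  cfg <- list(n_case_train = n_case_train, n_benign_train = n_benign_train,
              n_normal_train = n_normal_train, n_case_test = n_case_test,
              n_benign_test = n_benign_test, n_markers = n_markers,
              n_informative = n_informative, panel_true = panel_true,
              positivity_rate = positivity_rate,
              log_mean_baseline = log_mean_baseline, log_sd = log_sd,
              effect_log = effect_log, effect_log_weak = effect_log_weak,
              cross_reactive_weak = isTRUE(cross_reactive_weak),
              serum_marker_effect = serum_marker_effect,
              serum_positivity_rate = serum_positivity_rate,
              benign_shift = benign_shift, seed = seed)

  counts <- c("n_case_train", "n_benign_train", "n_normal_train",
              "n_case_test", "n_benign_test", "n_markers", "n_informative")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
      stop("invalid configuration: '", f, "' must be a positive integer",
           call. = FALSE)
    }
  }
  if (cfg$n_informative > cfg$n_markers) {
    stop("invalid configuration: 'n_informative' exceeds 'n_markers'",
         call. = FALSE)
  }
  if (!is.numeric(cfg$panel_true) || anyNA(cfg$panel_true) ||
      any(cfg$panel_true != round(cfg$panel_true)) ||
      any(cfg$panel_true < 1) || any(cfg$panel_true > cfg$n_informative) ||
      anyDuplicated(cfg$panel_true)) {
    stop("invalid configuration: 'panel_true' must be distinct indices in 1..n_informative",
         call. = FALSE)
  }
  for (f in c("positivity_rate", "serum_positivity_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid configuration: '", f, "' must be a probability in [0,1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$log_sd) || length(cfg$log_sd) != 1L ||
      is.na(cfg$log_sd) || cfg$log_sd <= 0) {
    stop("invalid configuration: 'log_sd' must be > 0", call. = FALSE)
  }
  for (f in c("effect_log", "effect_log_weak", "serum_marker_effect")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("invalid configuration: '", f, "' must be >= 0", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("invalid configuration: 'seed' must be a single integer", call. = FALSE)
  }
  class(cfg) <- "panel_sim_config"
  cfg
}

serum_marker_names <- function() {
  paste0(serum_prefix(), c("CYFRA21_1", "CEA", "SCCA", "NSE"))
}

#' Simulate a sample-by-marker autoantibody table with known ground truth
#'
#' Generates a training and test set of case/benign/normal sera measured on
#' `n_markers` autoantibody markers plus the 4 conventional serum tumor
#' markers, following the mixture model described in [panel_sim_config()].
#' The per-sample positivity indicators are returned as ground truth so that
#' marker-screening and panel-recovery behaviour can be tested against the
#' planted signal.
#'
#' @param config a [panel_sim_config()] object.
#' @return a list of class `panel_sim` with elements
#'   \describe{
#'     \item{table}{data frame with columns `sample_id`, `group`
#'       (case/benign/normal), `split` (train/test), one column per
#'       autoantibody marker (`AAb01`...), and serum-marker columns prefixed
#'       `stm_`. All abundance values are strictly positive.}
#'     \item{truth}{list with `informative_markers`, `panel_true` (marker
#'       names), and `per_sample_positivity` (samples x markers 0/1 matrix,
#'       identically zero for controls and non-informative markers).}
#'   }
#'   Identical config (including seed) reproduces the table exactly.
#' @examples
#' sim <- simulate_panel_data(panel_sim_config(
#'   n_case_train = 30, n_benign_train = 15, n_normal_train = 15,
#'   n_case_test = 20, n_benign_test = 20, seed = 7))
#' table(sim$table$group, sim$table$split)
#' @export
simulate_panel_data <- function(config = panel_sim_config()) {
  if (!inherits(config, "panel_sim_config")) {
    config <- do.call(panel_sim_config, as.list(config))
  }
  cfg <- config
  n_train <- cfg$n_case_train + cfg$n_benign_train + cfg$n_normal_train
  n_test <- cfg$n_case_test + cfg$n_benign_test
  n <- n_train + n_test
  group <- c(rep("case", cfg$n_case_train), rep("benign", cfg$n_benign_train),
             rep("normal", cfg$n_normal_train), rep("case", cfg$n_case_test),
             rep("benign", cfg$n_benign_test))
  split <- c(rep("train", n_train), rep("test", n_test))
  sample_id <- sprintf("S%04d", seq_len(n))
  markers <- sprintf("AAb%02d", seq_len(cfg$n_markers))
  informative <- markers[seq_len(cfg$n_informative)]
  panel <- informative[cfg$panel_true]
  weak <- setdiff(informative, panel)
  is_case <- group == "case"

  out <- with_seed(cfg$seed, {
    pos <- matrix(0L, n, cfg$n_markers, dimnames = list(sample_id, markers))
    # core-panel positivity: independent Bernoulli per (case, marker)
    pos[is_case, panel] <- matrix(
      rbinom(sum(is_case) * length(panel), 1L, cfg$positivity_rate),
      sum(is_case), length(panel))
    if (length(weak)) {
      if (cfg$cross_reactive_weak) {
        # weak markers inherit the positivity event of a paired core marker
        pair <- panel[((seq_along(weak) - 1L) %% length(panel)) + 1L]
        pos[, weak] <- pos[, pair, drop = FALSE]
      } else {
        pos[is_case, weak] <- matrix(
          rbinom(sum(is_case) * length(weak), 1L, cfg$positivity_rate),
          sum(is_case), length(weak))
      }
    }
    effect <- setNames(numeric(cfg$n_markers), markers)
    effect[panel] <- cfg$effect_log
    effect[weak] <- cfg$effect_log_weak

    logval <- matrix(rnorm(n * cfg$n_markers, cfg$log_mean_baseline, cfg$log_sd),
                     n, cfg$n_markers, dimnames = list(sample_id, markers))
    logval <- logval + pos %*% diag(effect, cfg$n_markers)
    if (cfg$benign_shift != 0) {
      logval[group == "benign", ] <- logval[group == "benign", ] + cfg$benign_shift
    }

    snames <- serum_marker_names()
    spos <- matrix(0L, n, length(snames), dimnames = list(sample_id, snames))
    spos[is_case, ] <- matrix(
      rbinom(sum(is_case) * length(snames), 1L, cfg$serum_positivity_rate),
      sum(is_case), length(snames))
    slog <- matrix(rnorm(n * length(snames), cfg$log_mean_baseline, cfg$log_sd),
                   n, length(snames), dimnames = list(sample_id, snames))
    slog <- slog + spos * cfg$serum_marker_effect

    tab <- data.frame(sample_id = sample_id, group = group, split = split,
                      exp(logval), exp(slog),
                      stringsAsFactors = FALSE, check.names = FALSE)
    rownames(tab) <- NULL
    list(table = tab, positivity = pos)
  })

  structure(list(
    table = out$table,
    truth = list(informative_markers = informative, panel_true = panel,
                 per_sample_positivity = out$positivity),
    config = cfg), class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  tb <- x$table
  cat("Synthetic autoantibody panel data\n")
  cat(sprintf("  %d samples (%d train, %d test), %d markers + %d serum markers\n",
              nrow(tb), sum(tb$split == "train"), sum(tb$split == "test"),
              length(marker_columns(tb)), length(serum_columns(tb))))
  cat("  planted core panel:", paste(x$truth$panel_true, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate second-round clone screening counts
#'
#' Emulates a second-round serological screen in which each candidate clone
#' is tested against a panel of `n_pos` cancer sera and `n_neg` healthy
#' sera. Truly reactive clones draw their true-positive count from
#' `Binomial(n_pos, tp_rate_true)` and their false-positive count from
#' `Binomial(n_neg, bg_rate)`; decoy clones draw both counts at the
#' background rate.
#'
#' @param n_clones number of clones.
#' @param n_true number of truly reactive clones (`<= n_clones`; they come
#'   first in the output).
#' @param n_pos,n_neg serum panel sizes (default 30 each).
#' @param tp_rate_true reactivity rate of true clones against cancer sera.
#' @param bg_rate background reactivity rate.
#' @param seed integer seed.
#' @return list with `counts` (data frame: `clone_id`, `tp`, `fp`, `n_pos`,
#'   `n_neg`) and `is_true` (logical ground-truth flags).
#' @seealso [screen_clones()]
#' @export
simulate_screen_counts <- function(n_clones, n_true, n_pos = 30, n_neg = 30,
                                   tp_rate_true, bg_rate, seed = 1) {
  for (f in c("tp_rate_true", "bg_rate")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid configuration: '", f, "' must be a probability in [0,1]",
           call. = FALSE)
    }
  }
  if (n_true > n_clones || n_true < 0) {
    stop("invalid configuration: 'n_true' must be in 0..n_clones", call. = FALSE)
  }
  with_seed(seed, {
    is_true <- seq_len(n_clones) <= n_true
    tp <- ifelse(is_true, rbinom(n_clones, n_pos, tp_rate_true),
                 rbinom(n_clones, n_pos, bg_rate))
    fp <- rbinom(n_clones, n_neg, bg_rate)
    list(counts = data.frame(clone_id = sprintf("clone_%03d", seq_len(n_clones)),
                             tp = tp, fp = fp, n_pos = n_pos, n_neg = n_neg,
                             stringsAsFactors = FALSE),
         is_true = is_true)
  })
}
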
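# Population decoding of call type: per-neuron window rates, pseudo-trial
# assembly across neurons, and Monte-Carlo resampled PCA + linear
# discriminant classification in sliding windows.

#' Per-trial mean firing rate in a window around vocal onset
#'
#' @param spikes A `spike_trains` object.
#' @param events `call_events` of one call type.
#' @param unit Unit index.
#' @param center_s Window center relative to vocal onset (s).
#' @param width_s Window width (default 1 s).
#' @return Numeric vector of rates (Hz), one per event whose window lies
#'   inside the recording (others dropped).
#' @export
neuron_window_rates <- function(spikes, events, unit = 1, center_s = 0,
                                width_s = 1) {
  st <- spikes$times[[unit]]
  lo <- events$onset_s + center_s - width_s / 2
  hi <- events$onset_s + center_s + width_s / 2
  ok <- lo >= 0
  if (is.finite(spikes$duration_s %||% NA)) ok <- ok & hi <= spikes$duration_s
  vapply(which(ok), function(i) {
    sum(st >= lo[i] & st < hi[i]) / width_s
  }, 0)
}

#' Assemble a two-class decoding dataset
#'
#' One entry per eligible neuron (>= `min_calls` trials of *each* class):
#' the per-trial window-mean rates for class A and class B.  Neurons from
#' different sessions are combined later by random trial pairing into
#' pseudo-trials inside [monte_carlo_lda()].
#'
#' @param neurons List of per-neuron lists with elements `a` and `b`
#'   (numeric per-trial rates), e.g. built with [neuron_window_rates()].
#' @param min_calls Eligibility threshold per class (default 20).
#' @return A `decoding_dataset`: eligible neurons, `n_neurons`.
#' @export
build_decoding_dataset <- function(neurons, min_calls = 20) {
  ok <- vapply(neurons, function(nr) {
    length(nr$a) >= min_calls && length(nr$b) >= min_calls
  }, TRUE)
  if (sum(ok) < 2) stop("need at least 2 eligible neurons")
  structure(list(neurons = neurons[ok], n_neurons = sum(ok)),
            class = "decoding_dataset")
}

# Draw n pseudo-trials for one class: each pseudo-trial pairs one
# independently sampled trial (with replacement) per neuron from `pools`
# (a list of per-neuron trial-rate vectors).
draw_pseudo <- function(pools, n) {
  vapply(pools, function(p) p[sample.int(length(p), n, replace = TRUE)],
         numeric(n))
}

#' Monte-Carlo linear-discriminant decoding accuracy
#'
#' Per repetition: each neuron's trials of each class are split 70/30 into
#' train/test pools; `n_redraw` bootstrap pseudo-trials per class are drawn
#' from each pool; a principal-component projection (up to `n_pc`
#' components, capped at the feature dimension) is fit on the training
#' draws only; a shared-covariance linear discriminant is fit on the
#' projected training draws and scored on the projected test draws.  The
#' mean and percentile 95% CI of accuracy over `n_rep` repetitions are
#' returned; chance level is 0.5.
#'
#' @param dataset A `decoding_dataset`.
#' @param train_frac Training fraction (default 0.7).
#' @param n_redraw Pseudo-trials per class per pool (default 5000).
#' @param n_pc Maximum principal components (default 10).
#' @param n_rep Repetitions (default 500).
#' @param seed Integer seed.
#' @return A `decoding_result`: `mean_acc`, `ci` (2.5/97.5 percentiles),
#'   `acc` (per-rep), `significant` (CI excludes 0.5), `n_neurons`.
#' @export
monte_carlo_lda <- function(dataset, train_frac = 0.7, n_redraw = 5000,
                            n_pc = 10, n_rep = 500, seed = 1) {
  nrn <- dataset$neurons
  n_feat <- length(nrn)
  min_n <- min(vapply(nrn, function(x) min(length(x$a), length(x$b)), 0L))
  if (min_n < 4) stop("need at least ~4 trials per class per neuron")
  set.seed(substream_seed(seed, "mclda"))
  acc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    repeat {
      pools <- lapply(c("a", "b"), function(cl) {
        lapply(nrn, function(x) {
          v <- x[[cl]]
          ntr <- round(train_frac * length(v))
          idx <- sample.int(length(v), ntr)
          list(train = v[idx], test = v[-idx])
        })
      })
      tr_a <- draw_pseudo(lapply(pools[[1]], `[[`, "train"), n_redraw)
      tr_b <- draw_pseudo(lapply(pools[[2]], `[[`, "train"), n_redraw)
      te_a <- draw_pseudo(lapply(pools[[1]], `[[`, "test"), n_redraw)
      te_b <- draw_pseudo(lapply(pools[[2]], `[[`, "test"), n_redraw)
      train <- rbind(tr_a, tr_b)
      test <- rbind(te_a, te_b)
      labels <- factor(rep(c("a", "b"), each = n_redraw))
      pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
      keep <- which(pc$sdev > 1e-10)
      k <- min(n_pc, n_feat, length(keep))
      if (k < 1) next  # degenerate redraw; resample
      tr_sc <- pc$x[, seq_len(k), drop = FALSE]
      te_sc <- scale(test, center = pc$center, scale = FALSE) %*%
        pc$rotation[, seq_len(k), drop = FALSE]
      fit <- tryCatch(MASS::lda(tr_sc, grouping = labels),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- stats::predict(fit, te_sc)$class
      acc[r] <- mean(pred == labels)
      break
    }
  }
  ci <- unname(stats::quantile(acc, c(0.025, 0.975)))
  structure(list(mean_acc = mean(acc), ci = ci, acc = acc,
                 significant = ci[1] > 0.5 || ci[2] < 0.5,
                 n_neurons = n_feat),
            class = "decoding_result")
}

#' Sliding-window decoding curve
#'
#' Runs [monte_carlo_lda()] at each window center: per center, per-neuron
#' per-trial rates are taken in a `width_s` window, eligibility is
#' re-checked, and accuracy with its 95% CI is recorded.
#'
#' @param spikes A `spike_trains` object (one synthetic session; multiple
#'   sessions can be decoded by concatenating their neuron rate lists with
#'   [build_decoding_dataset()] and [monte_carlo_lda()] directly).
#' @param events_a,events_b `call_events` of the two classes.
#' @param centers Window centers (s relative to onset), default
#'   `seq(-3, 3, by = 0.5)`.
#' @param width_s Window width (default 1 s).
#' @param units Unit indices (default all).
#' @param min_calls Per-class eligibility threshold (default 20).
#' @param ... Passed to [monte_carlo_lda()] (`n_redraw`, `n_rep`, ...).
#' @param seed Integer seed; each center uses an independent substream.
#' @return A `decoding_curve` data frame: `center_s`, `mean_acc`, `ci_lo`,
#'   `ci_hi`, `significant`.
#' @export
sliding_decoding_curve <- function(spikes, events_a, events_b,
                                   centers = seq(-3, 3, by = 0.5),
                                   width_s = 1,
                                   units = seq_along(spikes$times),
                                   min_calls = 20, seed = 1, ...) {
  stopifnot(!is.unsorted(centers))
  rows <- lapply(seq_along(centers), function(j) {
    ctr <- centers[j]
    neurons <- lapply(units, function(u) {
      list(a = neuron_window_rates(spikes, events_a, u, ctr, width_s),
           b = neuron_window_rates(spikes, events_b, u, ctr, width_s))
    })
    ds <- build_decoding_dataset(neurons, min_calls = min_calls)
    res <- monte_carlo_lda(ds, seed = substream_seed(seed,
                                                     paste0("ctr", j)), ...)
    data.frame(center_s = ctr, mean_acc = res$mean_acc,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               significant = res$significant)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("decoding_curve", "data.frame")
  out
}
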
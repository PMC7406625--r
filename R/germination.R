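## Seed-dormancy traits from cumulative germination counts.
##
## G3d / G7d: cumulative germination percentage at 72 h / 168 h.
## T50: time to reach germination of 50% of the tested seeds, linearly
## interpolated at the first upward crossing; lines never reaching 50% are
## censored at 168 h and flagged.
## AUC: trapezoidal integral of the cumulative percentage curve over
## [0, 168] h (%.h), a germination-uniformity summary.

#' Convert cumulative germinated counts to a germination curve
#'
#' @param counts integer cumulative germinated counts, one per scoring
#'   time; must be non-decreasing and at most `n_seeds`.
#' @param n_seeds number of seeds tested (50 in the standard assay).
#' @param timepoints scoring times in hours (default 24 h steps over 7
#'   days); a `time = 0, fraction = 0` point is prepended.
#' @param line,replicate optional identifiers carried through.
#' @return a `germination_curve` data.frame with columns `time` and
#'   `fraction`.
#' @export
cumulative_fractions <- function(counts, n_seeds,
                                 timepoints = seq(24, 168, by = 24),
                                 line = NA_character_, replicate = NA_integer_) {
  stopifnot(length(counts) == length(timepoints), all(diff(timepoints) > 0),
            n_seeds >= 1)
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers")
  }
  if (any(diff(counts) < 0)) stop("cumulative counts decrease: corrupt input")
  if (any(counts > n_seeds)) stop("count exceeds n_seeds")
  curve <- data.frame(time = c(0, timepoints),
                      fraction = c(0, counts / n_seeds))
  attr(curve, "n_seeds") <- n_seeds
  attr(curve, "line") <- line
  attr(curve, "replicate") <- replicate
  class(curve) <- c("germination_curve", "data.frame")
  curve
}

validate_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("time", "fraction") %in% names(curve)))
  if (any(diff(curve$time) <= 0)) stop("timepoints must be strictly increasing")
  if (any(diff(curve$fraction) < 0)) stop("fractions must be non-decreasing")
  if (any(curve$fraction < 0 | curve$fraction > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  invisible(curve)
}

#' Extract the four dormancy traits from one germination curve
#'
#' @param curve a `germination_curve` (or any data.frame with strictly
#'   increasing `time` and non-decreasing `fraction` in `[0, 1]`).
#' @param horizon end of the assay in hours (G7d and the AUC upper limit).
#' @return one-row data.frame: `G3d`, `G7d` (percent), `T50` (hours;
#'   censored at `horizon` with `T50_censored = TRUE` when 50% of the
#'   tested seeds is never reached), `AUC` (percent-hours over
#'   `[0, horizon]`).
#' @examples
#' cv <- cumulative_fractions(c(10, 20, 20, 30, 40, 40, 40), 50)
#' germination_params(cv)
#' @export
germination_params <- function(curve, horizon = 168) {
  validate_curve(curve)
  t <- curve$time
  f <- curve$fraction
  at_or_before <- function(target) {
    i <- which(t <= target)
    if (!length(i)) stop("no observation at or before ", target, " h")
    if (max(t[i]) < target) {
      dq_log(sprintf("germination_params: no %g h observation; using %g h",
                     target, max(t[i])))
    }
    f[max(i)]
  }
  g3d <- 100 * at_or_before(72)
  g7d <- 100 * at_or_before(horizon)
  sel <- t <= horizon
  auc <- pracma::trapz(t[sel], 100 * f[sel])
  if (max(t[sel]) < horizon) { # extend flat to the horizon if needed
    auc <- auc + (horizon - max(t[sel])) * 100 * f[max(which(sel))]
  }
  if (f[1] >= 0.5) {
    t50 <- t[1]
    censored <- FALSE
  } else if (max(f) < 0.5) {
    t50 <- horizon
    censored <- TRUE
  } else {
    i <- min(which(f >= 0.5)) # first upward crossing of 50% of seeds
    t50 <- t[i - 1] + (t[i] - t[i - 1]) * (0.5 - f[i - 1]) / (f[i] - f[i - 1])
    censored <- FALSE
  }
  data.frame(G3d = g3d, G7d = g7d, T50 = t50, T50_censored = censored,
             AUC = auc)
}

#' Trait table for a tidy table of germination counts
#'
#' @param counts tidy data.frame with columns `line`, `replicate`, `hour`,
#'   `cumulative_count`, `n_seeds` (as written by the simulator or read
#'   from CSV).
#' @return data.frame with one row per line x replicate and the four
#'   traits.
#' @export
germination_trait_table <- function(counts) {
  need <- c("line", "replicate", "hour", "cumulative_count", "n_seeds")
  stopifnot(all(need %in% names(counts)))
  out <- lapply(split(counts, list(counts$line, counts$replicate),
                      drop = TRUE), function(d) {
    d <- d[order(d$hour), ]
    cv <- cumulative_fractions(d$cumulative_count, d$n_seeds[1],
                               timepoints = d$hour)
    cbind(line = d$line[1], replicate = d$replicate[1],
          germination_params(cv))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line, res$replicate), ]
}

#' Aggregate replicate traits to line means
#'
#' Censored T50 replicates contribute the censoring value (168 h) so that
#' dormant lines keep a rank-consistent penalty instead of dropping out;
#' a line is flagged when any replicate was censored.
#'
#' @param params per-replicate trait table from
#'   [germination_trait_table()].
#' @return data.frame with per-line trait means, standard deviations, the
#'   replicate count and the `T50_any_censored` flag.
#' @export
aggregate_replicates <- function(params) {
  stopifnot(all(c("line", "G3d", "G7d", "T50", "AUC") %in% names(params)))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- lapply(split(params, params$line), function(d) {
    data.frame(line = d$line[1],
               G3d = mean(d$G3d), G3d_sd = sd0(d$G3d),
               G7d = mean(d$G7d), G7d_sd = sd0(d$G7d),
               T50 = mean(d$T50), T50_sd = sd0(d$T50),
               AUC = mean(d$AUC), AUC_sd = sd0(d$AUC),
               n_replicates = nrow(d),
               T50_any_censored = any(d$T50_censored))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line), ]
}

#' Read / write tidy germination count tables
#'
#' @param counts tidy counts data.frame (see
#'   [germination_trait_table()]).
#' @param path CSV file.
#' @export
write_germination_counts <- function(counts, path) {
  utils::write.csv(counts, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_germination_counts
#' @export
read_germination_counts <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
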
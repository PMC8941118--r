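# Four-parameter circular replichore model and its fitting machinery.
#
# The model describes a cumulative skew track as a circular piecewise-linear
# curve: slope +alpha1 on the leading arc (fraction `div` of the chromosome,
# starting at fraction `shift`), slope -alpha2 on the complementary lagging
# arc, anchored so the predicted value at position 0 is 0 (cumulative counters
# start at zero). alpha1 = 0.046 means 46 excess bases per 1000 nucleotides of
# leading strand. Circular closure is deliberately NOT enforced: the final
# cumulative value equals the total base excess of the sequence, which real
# chromosomes (Chargaff deviations) keep nonzero.

#' Construct replichore model parameters
#'
#' @param alpha1 Per-nucleotide skew slope on the leading strand.
#' @param alpha2 Per-nucleotide slope magnitude on the lagging strand (the
#'   modeled slope there is `-alpha2`).
#' @param div Leading-strand fraction, in (0, 1).
#' @param shift Origin offset as fraction of chromosome length, in [0, 1).
#' @param rms Normalized goodness-of-fit (RMSE / |mean skew|), if known.
#' @return An object of class `fit_params`.
#' @export
fit_params <- function(alpha1, alpha2, div = 0.5, shift = 0, rms = NA_real_) {
  if (div <= 0 || div >= 1) stop("div must lie strictly inside (0, 1)")
  if (shift < 0 || shift >= 1) stop("shift must lie in [0, 1)")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, div = div, shift = shift,
                 rms = rms),
            class = "fit_params")
}

#' @export
print.fit_params <- function(x, ...) {
  cat(sprintf(
    "<fit_params> alpha1=%.5g alpha2=%.5g div=%.4f shift=%.4f rms=%.4g\n",
    x$alpha1, x$alpha2, x$div, x$shift, x$rms))
  invisible(x)
}

# Length of [0, p) that intersects the leading arc [shift, shift+div)*L,
# vectorized over p. Exact closed form; the arc may wrap past L.
leading_overlap <- function(p, length, div, shift) {
  lo <- shift * length
  hi <- (shift + div) * length
  if (hi <= length) {
    pmax(0, pmin(p, hi) - lo)
  } else {
    pmax(0, pmin(p, length) - lo) + pmin(p, hi - length)
  }
}

#' Evaluate the replichore model at given positions
#'
#' Exact closed-form evaluation of the anchored piecewise-linear curve: the
#' value at position `p` is `alpha1 * A(p) - alpha2 * (p - A(p))` where `A(p)`
#' is the number of leading-arc nucleotides in `[0, p)`.
#'
#' @param params A `fit_params` object.
#' @param length Chromosome length `L` in nucleotides.
#' @param positions Offsets in `[0, L]` at which to evaluate.
#' @return Numeric vector of predicted cumulative values.
#' @examples
#' p <- fit_params(0.046, 0.046, div = 0.5, shift = 0)
#' model_eval(p, 1e6, 5e5) # 23000
#' @export
model_eval <- function(params, length, positions) {
  if (params$div <= 0 || params$div >= 1 ||
      params$shift < 0 || params$shift >= 1) {
    stop("div must be in (0,1) and shift in [0,1)")
  }
  a <- leading_overlap(positions, length, params$div, params$shift)
  params$alpha1 * a - params$alpha2 * (positions - a)
}

#' Normalized goodness-of-fit
#'
#' Root-mean-squared error of the fit divided by the absolute mean of the
#' observed skew; the normalization avoids penalizing good fits on strongly
#' skewed chromosomes. When the observed mean is below machine epsilon the
#' ratio is undefined and `+Inf` is returned as a sentinel rather than an
#' error.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
goodness <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop("observed and predicted must have equal positive length")
  }
  rmse <- sqrt(mean((observed - predicted)^2))
  m <- abs(mean(observed))
  if (m < .Machine$double.eps) return(Inf)
  rmse / m
}

#' Canonicalize fitted parameters
#'
#' The optimizer is free to describe the same curve with the arcs swapped
#' (e.g. for chromosome files sequenced in the non-canonical direction, or
#' with the origin of replication away from the start of the file). When the
#' fitted `alpha1` is negative the arcs are relabeled -- alpha roles swapped
#' and negated, `div -> 1 - div`, `shift -> (shift + div) mod 1` -- so that
#' the rising-GC arc is reported as leading. The described curve (and hence
#' the fit error) is unchanged. `shift` is always wrapped into [0, 1).
#'
#' @param params A `fit_params` object (possibly raw optimizer output).
#' @return Canonicalized `fit_params`.
#' @export
canonicalize <- function(params) {
  rms <- if (is.null(params$rms)) NA_real_ else params$rms
  if (params$alpha1 < 0) {
    fit_params(alpha1 = -params$alpha2, alpha2 = -params$alpha1,
               div = 1 - params$div,
               shift = (params$shift + params$div) %% 1,
               rms = rms)
  } else {
    fit_params(alpha1 = params$alpha1, alpha2 = params$alpha2,
               div = params$div, shift = params$shift %% 1, rms = rms)
  }
}

fit_objective <- function(par, length, positions, values) {
  div <- par[3]
  if (!is.finite(div) || div <= 1e-4 || div >= 1 - 1e-4) {
    return(1e12 * (1 + abs(div)))
  }
  shift <- par[4] %% 1
  a <- leading_overlap(positions, length, div, shift)
  pred <- par[1] * a - par[2] * (positions - a)
  sqrt(mean((values - pred)^2))
}

#' Fit the four-parameter replichore model to a skew track
#'
#' Minimizes the RMSE between [model_eval()] and the observed checkpoint
#' values over `(alpha1, alpha2, div, shift)` using Nelder-Mead downhill
#' simplex optimization with multiple starting points. The first start follows
#' the average observed skew over the whole genome with no shift and evenly
#' distributed strands (`alpha1 = alpha2 = |final|/L`, `div = 0.5`,
#' `shift = 0`); the remaining starts place `shift` on a deterministic grid
#' (0.1, 0.2, ..., 0.9), covering the one strongly multi-modal axis. The best
#' result (lowest RMSE, ties broken by smallest shift) is polished by one
#' further simplex restart, then canonicalized; `rms` is the normalized
#' goodness-of-fit.
#'
#' @param track A `skew_track` with at least 8 checkpoints.
#' @param length Chromosome length in nucleotides.
#' @param starts Number of starting points (default 10).
#' @return A canonicalized `fit_params` with `rms` populated.
#' @export
fit_four_param <- function(track, length, starts = 10L) {
  stopifnot(inherits(track, "skew_track"), starts >= 1L)
  pos <- track$positions
  obs <- track$values
  if (length(pos) < 8L) stop("track must have at least 8 checkpoints")
  if (all(obs == 0)) stop("degenerate all-zero track: goodness undefined")

  a0 <- abs(obs[length(obs)]) / length
  if (a0 == 0) a0 <- max(abs(obs)) / length
  shift_grid <- c(0, seq(0.1, 0.9, by = 0.1))[seq_len(min(starts, 10L))]
  if (starts > 10L) {
    shift_grid <- c(shift_grid, seq_len(starts - 10L) / (starts - 9L))
  }

  ctrl <- list(reltol = 1e-10, maxit = 2000L)
  run <- function(par) {
    stats::optim(par, fit_objective, method = "Nelder-Mead", control = ctrl,
                 length = length, positions = pos, values = obs)
  }
  best <- NULL
  for (s0 in shift_grid) {
    fit <- run(c(a0, a0, 0.5, s0))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         (fit$par[4] %% 1) < (best$par[4] %% 1))) {
      best <- fit
    }
  }
  # polish: restart the simplex at its own optimum to tighten convergence
  for (i in 1:2) best <- run(best$par)

  par <- best$par
  raw <- fit_params(alpha1 = par[1], alpha2 = par[2],
                    div = min(max(par[3], 1e-4), 1 - 1e-4),
                    shift = par[4] %% 1)
  out <- canonicalize(raw)
  out$rms <- goodness(obs, model_eval(out, length, pos))
  out
}

#' Fit leading/lagging slopes with div and shift held fixed
#'
#' GC skew tends to be the most strongly defined skew and is therefore used to
#' pick `div` and `shift`; every other skew is then fitted under those fixed
#' constraints. With the arc geometry frozen the model is linear in
#' `(alpha1, alpha2)`, so the RMSE-optimal slopes are obtained exactly by
#' least squares (the exact minimizer of the same objective the simplex would
#' optimize). Slopes may come out negative: skews discordant with GC are real
#' (e.g. TA skew in Firmicutes).
#'
#' @param track A `skew_track`.
#' @param length Chromosome length in nucleotides.
#' @param div,shift Arc geometry from the GC fit.
#' @return A list with `alpha1`, `alpha2`, `rms`.
#' @export
fit_constrained <- function(track, length, div, shift) {
  stopifnot(inherits(track, "skew_track"))
  if (div <= 0 || div >= 1) stop("div must lie strictly inside (0, 1)")
  shift <- shift %% 1
  pos <- track$positions
  obs <- track$values
  a <- leading_overlap(pos, length, div, shift)
  x <- cbind(a, -(pos - a))
  coef <- tryCatch(qr.coef(qr(x), obs), error = function(e) c(0, 0))
  coef[is.na(coef)] <- 0
  pred <- x %*% coef
  list(alpha1 = coef[[1]], alpha2 = coef[[2]],
       rms = goodness(obs, as.numeric(pred)))
}

#' Analyze one chromosome: scan profile to full fit set
#'
#' Fits the four-parameter model to the GC track, then constrained
#' two-parameter fits (shared `div`/`shift`) for TA, the six codon-position
#' skews, the two non-coding skews and the strand-bias counter.
#'
#' @param profile A `scan_profile`.
#' @param starts Number of starting points for the GC fit.
#' @return A `chromosome_result`: list with `accession`, `length`, `div`,
#'   `shift`, `gc` (full `fit_params`) and `constrained`, a named list of
#'   `alpha1`/`alpha2`/`rms` triplets for
#'   `ta, gc0, gc1, gc2, ta0, ta1, ta2, gcng, tang, sb`.
#' @export
analyze_profile <- function(profile, starts = 10L) {
  stopifnot(inherits(profile, "scan_profile"))
  gc_fit <- fit_four_param(profile_track(profile, "gcskew"), profile$length,
                           starts = starts)
  cols <- c(ta = "taskew", gc0 = "gcskew0", gc1 = "gcskew1", gc2 = "gcskew2",
            ta0 = "taskew0", ta1 = "taskew1", ta2 = "taskew2",
            gcng = "gcskewNG", tang = "taskewNG", sb = "pospos")
  constrained <- lapply(cols, function(cn) {
    fit_constrained(profile_track(profile, cn), profile$length,
                    div = gc_fit$div, shift = gc_fit$shift)
  })
  structure(
    list(accession = profile$accession, length = profile$length,
         div = gc_fit$div, shift = gc_fit$shift, gc = gc_fit,
         constrained = constrained),
    class = "chromosome_result"
  )
}

#' @export
print.chromosome_result <- function(x, ...) {
  cat(sprintf(
    "<chromosome_result> %s: alpha1gc=%.5g alpha2gc=%.5g div=%.4f shift=%.4f gcRMS=%.4g\n",
    x$accession, x$gc$alpha1, x$gc$alpha2, x$div, x$shift, x$gc$rms))
  invisible(x)
}

#' Asymmetry flags for a fitted chromosome
#'
#' Flags the two anomaly classes surfaced by replichore fits: skew asymmetry
#' (one strand's GC skew slope at least 3 times the other's, boundary
#' inclusive) and strand-length asymmetry (one replication strand at least 3
#' times as long as the other). A zero minimum slope counts as asymmetric
#' (infinite ratio).
#'
#' @param result A `chromosome_result` (or a `fit_params` for the GC fit).
#' @param ratio Threshold ratio (default 3).
#' @return Named logical vector `c(skew_asymmetric=, strand_asymmetric=)`.
#' @export
asymmetry_flags <- function(result, ratio = 3) {
  gc <- if (inherits(result, "chromosome_result")) result$gc else result
  slopes <- abs(c(gc$alpha1, gc$alpha2))
  skew_asym <- if (min(slopes) == 0) TRUE else max(slopes) >= ratio * min(slopes)
  arms <- c(gc$div, 1 - gc$div)
  strand_asym <- max(arms) >= ratio * min(arms)
  c(skew_asymmetric = skew_asym, strand_asymmetric = strand_asym)
}

#' Codon-bias times strand-bias product
#'
#' The gene-driven component of skew is, to first order, the product of codon
#' bias and strand bias: genes rich in G that crowd the leading strand create
#' GC skew by themselves. Codon bias enters as the signed G excess among
#' coding G+C nucleotides, `2*ggcfrac - 1`; strand bias as the fitted
#' leading-strand slope of the strand-bias counter. For an all-leading-strand,
#' all-G coding genome the product equals the coding density.
#'
#' @param ggcfrac G fraction of coding G+C nucleotides (from
#'   [coding_composition()]).
#' @param strand_bias_slope Fitted `alpha1` of the `sb` track.
#' @return The product, a dimensionless predicted-skew scale.
#' @export
bias_product <- function(ggcfrac, strand_bias_slope) {
  (2 * ggcfrac - 1) * strand_bias_slope
}
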
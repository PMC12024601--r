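#' Factor specification for the REBA response surface
#'
#' Four factors: neck (N), trunk (T), upper arm (U.A) and lower arm (L.A),
#' each with low and high natural levels. Legs and wrist are excluded from
#' the surface because they are constant (1 and 2) across the seated
#' profiles the surface models. The default ranges are the min/max of the
#' bundled seated-subject survey points: N 2-3, T 3-5, U.A 3-6, L.A 1-2.
#'
#' @param low,high numeric length-4 vectors of natural levels, named or in
#'   the order N, T, U.A, L.A.
#' @return object of class `factor_spec`.
#' @export
factor_spec <- function(low = c(N = 2, T = 3, U.A = 3, L.A = 1),
                        high = c(N = 3, T = 5, U.A = 6, L.A = 2)) {
  low <- as.numeric(low); high <- as.numeric(high)
  stopifnot(length(low) == 4L, length(high) == 4L, all(low < high))
  structure(list(labels = c("N", "T", "U.A", "L.A"), low = low, high = high),
            class = "factor_spec")
}

#' Generate a four-factor Box-Behnken design
#'
#' All six factor pairs at the four (+/-1, +/-1) edge combinations with the
#' remaining factors at the center (24 runs), plus `center_replicates`
#' all-center runs. Natural levels decode linearly: -1 = low, +1 = high,
#' 0 = midpoint.
#'
#' @param factors a [factor_spec()] (exactly four factors).
#' @param center_replicates number of center-point replicates (>= 0).
#' @return object of class `bbd_design`: list with `coded` and `natural`
#'   run matrices (and later `response` once scored).
#' @export
#' @examples
#' nrow(bbd_design(factor_spec(), 4)$coded)  # 28 runs
bbd_design <- function(factors = factor_spec(), center_replicates = 4L) {
  if (!inherits(factors, "factor_spec") || length(factors$low) != 4L) {
    stop("unsupported design: exactly four factors are required",
         call. = FALSE)
  }
  stopifnot(center_replicates >= 0, center_replicates == round(center_replicates))
  pairs <- utils::combn(4, 2)
  edges <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  coded <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    m <- matrix(0, nrow = 4, ncol = 4)
    m[, pairs[1, k]] <- edges[, 1]
    m[, pairs[2, k]] <- edges[, 2]
    m
  }))
  if (center_replicates > 0) {
    coded <- rbind(coded, matrix(0, center_replicates, 4))
  }
  colnames(coded) <- factors$labels
  mid <- (factors$low + factors$high) / 2
  half <- (factors$high - factors$low) / 2
  natural <- sweep(sweep(coded, 2, half, `*`), 2, mid, `+`)
  structure(list(factors = factors, coded = coded, natural = natural,
                 response = NULL), class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("<bbd_design> %d runs, 4 factors (%s)%s\n", nrow(x$coded),
              paste(x$factors$labels, collapse = ", "),
              if (is.null(x$response)) "" else ", scored"))
  invisible(x)
}

#' Round half away from zero (chart levels are integers)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Score a design's runs with the REBA chart
#'
#' Each run's natural levels give the neck, trunk, upper-arm and lower-arm
#' points; legs and wrist are held fixed. The chart is integer-only, so
#' fractional levels (center-point midpoints such as neck 2.5) need a
#' convention:
#' * `"interpolate"` (default): multilinear interpolation of the chart
#'   total over the neighboring integer corners. This keeps the response
#'   faithful to the chart at integer levels while avoiding the level
#'   quantization that badly conditions a first-order fit; it is the only
#'   convention under which the 28-run fit reaches the reference fit
#'   quality (adjusted R-squared about 0.9).
#' * `"half_up"`, `"half_down"`, `"half_even"`: round the level to an
#'   integer first, then look up the chart.
#'
#' The design keeps its continuous natural levels for regression.
#'
#' @param design a [bbd_design()].
#' @param legs,wrist fixed leg and wrist points (defaults 1 and 2, the
#'   constant values of the seated profiles).
#' @param adj an [adjustments()] object.
#' @param level_rounding how to score fractional levels, see Details.
#' @return the design with `$response` filled (REBA totals per run).
#' @export
score_design <- function(design, legs = 1L, wrist = 2L, adj = adjustments(),
                         level_rounding = c("interpolate", "half_up",
                                            "half_down", "half_even")) {
  stopifnot(inherits(design, "bbd_design"))
  level_rounding <- match.arg(level_rounding)
  chart <- function(lv) {
    reba_total(reba_points(neck = lv[1], trunk = lv[2], legs = legs,
                           upper_arm = lv[3], lower_arm = lv[4],
                           wrist = wrist), adj)$total
  }
  score_one <- function(lv) {
    if (level_rounding != "interpolate") {
      r <- switch(level_rounding,
                  half_up = round_half_up(lv),
                  half_down = ceiling(lv - 0.5),
                  half_even = round(lv))
      return(chart(r))
    }
    los <- floor(lv); w <- lv - los
    tot <- 0
    for (m in 0:15) {
      bits <- as.integer(intToBits(m))[1:4]
      wt <- prod(ifelse(bits == 1, w, 1 - w))
      if (wt > 0) tot <- tot + wt * chart(los + bits)
    }
    tot
  }
  design$response <- apply(design$natural, 1, score_one)
  design
}

#' Fit a first-order (linear) response-surface model
#'
#' Ordinary least squares of the response on the four natural factor
#' levels. Reports R-squared, adjusted R-squared (n - p - 1 denominator),
#' predicted R-squared from the PRESS (leave-one-out prediction residual)
#' statistic, and a per-term ANOVA with F = t^2 and the model F test.
#'
#' @param design a scored [bbd_design()] (see [score_design()]), or a data
#'   frame whose first four columns are the factor levels and whose
#'   `response` column is the response.
#' @return object of class `reba_lm`: list with `intercept`,
#'   `coefficients` (N, T, U.A, L.A), `r2`, `adjusted_r2`, `predicted_r2`,
#'   `anova` (per-term F and p plus the model row) and `fit` (the
#'   underlying `lm`).
#' @export
fit_linear <- function(design) {
  if (inherits(design, "bbd_design")) {
    if (is.null(design$response)) {
      stop("design has no responses; call score_design() first", call. = FALSE)
    }
    df <- as.data.frame(design$natural)
    df$response <- design$response
  } else {
    df <- as.data.frame(design)
    stopifnot("response" %in% names(df))
  }
  labels <- setdiff(names(df), "response")[1:4]
  if (nrow(df) < 6L) stop("need at least 6 runs to fit", call. = FALSE)
  X <- as.matrix(df[, labels])
  if (qr(cbind(1, X))$rank < 5L) {
    stop("rank-deficient design matrix; cannot fit linear model",
         call. = FALSE)
  }
  names(df)[seq_along(labels)] <- make.names(labels)
  fml <- stats::reformulate(make.names(labels), response = "response")
  fit <- stats::lm(fml, data = df)
  # summary.lm warns on numerically perfect fits; harmless here
  sm <- suppressWarnings(summary(fit))
  n <- nrow(df); p <- 4L
  press <- sum((stats::residuals(fit) / (1 - stats::lm.influence(fit)$hat))^2)
  sst <- sum((df$response - mean(df$response))^2)
  coefs <- stats::coef(fit)
  tvals <- sm$coefficients[-1, "t value"]
  pvals <- sm$coefficients[-1, "Pr(>|t|)"]
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  anova_tab <- data.frame(
    term = c("Model", labels),
    F = c(unname(fstat[1]), unname(tvals^2)),
    p = c(unname(model_p), unname(pvals)))
  structure(list(intercept = unname(coefs[1]),
                 coefficients = stats::setNames(unname(coefs[-1]), labels),
                 r2 = sm$r.squared,
                 adjusted_r2 = 1 - (1 - sm$r.squared) * (n - 1) / (n - p - 1),
                 predicted_r2 = 1 - press / sst,
                 press = press,
                 anova = anova_tab,
                 residuals = unname(stats::residuals(fit)),
                 fit = fit), class = "reba_lm")
}

#' Construct a linear REBA model from fixed coefficients
#'
#' Builds a `reba_lm` directly from an intercept and the four factor
#' coefficients, without fit statistics. Used to pin a published or
#' previously fitted calibration.
#'
#' @param intercept numeric intercept.
#' @param coefficients numeric length-4 vector for N, T, U.A, L.A.
#' @return a `reba_lm` (without `fit`/ANOVA components).
#' @export
linear_model <- function(intercept, coefficients) {
  stopifnot(length(coefficients) == 4L, is.finite(intercept),
            all(is.finite(coefficients)))
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                c("N", "T", "U.A", "L.A")),
                 r2 = NA_real_, adjusted_r2 = NA_real_,
                 predicted_r2 = NA_real_, anova = NULL, fit = NULL),
            class = "reba_lm")
}

#' Reference linear REBA model
#'
#' The pinned first-order calibration of the REBA chart over the seated
#' factor ranges (N 2-3, T 3-5, U.A 3-6, L.A 1-2, legs 1, wrist 2):
#' `REBA = -1.53635 + 1.049 N + 1.0 T + 0.925148 U.A + 0.865374 L.A`.
#' Used as the default predictor for point-profile screening and as the
#' default model for desirability optimization examples.
#'
#' @return a `reba_lm`.
#' @export
reference_model <- function() {
  linear_model(-1.53635, c(1.049, 1.0, 0.925148, 0.865374))
}

#' Predict the REBA response of a linear model
#'
#' Affine evaluation `intercept + sum(coef * level)`. With
#' `rounded = TRUE` the prediction is rounded to the nearest integer for
#' comparison against chart scores.
#'
#' @param object a `reba_lm`.
#' @param levels numeric length-4 vector (N, T, U.A, L.A) or a matrix/data
#'   frame with four columns.
#' @param rounded round to nearest integer score.
#' @param ... unused.
#' @return predicted response(s).
#' @export
predict.reba_lm <- function(object, levels, rounded = FALSE, ...) {
  m <- if (is.null(dim(levels))) matrix(as.numeric(levels), ncol = 4)
  else as.matrix(levels)
  stopifnot(ncol(m) == 4L, all(is.finite(m)))
  out <- as.numeric(object$intercept + m %*% object$coefficients)
  if (rounded) round_half_up(out) else out
}

#' @export
print.reba_lm <- function(x, ...) {
  cat(sprintf("<reba_lm> REBA = %.5g + %s\n", x$intercept,
              paste(sprintf("%.5g %s", x$coefficients,
                            names(x$coefficients)), collapse = " + ")))
  if (!is.na(x$r2)) {
    cat(sprintf("R2 %.4f, adj %.4f, pred %.4f\n", x$r2, x$adjusted_r2,
                x$predicted_r2))
  }
  invisible(x)
}

#' Desirability optimization of a REBA response surface
#'
#' Single-response Derringer-Suich desirability over the factor box:
#' for `goal = "maximize"`, `d = (yhat - L) / (H - L)`; for
#' `goal = "minimize"`, `d = (H - yhat) / (H - L)`; both clipped to
#' `[0, 1]`. The desirability is optimized by multi-start bounded
#' quasi-Newton search (default 100 starts, mirroring the usual
#' response-surface software setting) and the unique solutions are returned
#' ranked by desirability.
#'
#' @param model a `reba_lm`.
#' @param factors a [factor_spec()] giving the box.
#' @param goal `"minimize"` or `"maximize"`.
#' @param response_bounds `c(L, H)` anchoring the desirability ramp;
#'   default: the model's predicted range over the box corners (the
#'   response range of the design).
#' @param starts number of random starts (>= 1).
#' @param seed integer seed; identical seeds give identical ranked
#'   solutions.
#' @return object of class `reba_optimization`: list with `solutions`
#'   (data frame of levels, predicted response, desirability, ranked
#'   descending) and `goal`.
#' @export
optimize_desirability <- function(model, factors = factor_spec(),
                                  goal = c("minimize", "maximize"),
                                  response_bounds = NULL, starts = 100L,
                                  seed = 1L) {
  goal <- match.arg(goal)
  stopifnot(inherits(model, "reba_lm"), inherits(factors, "factor_spec"),
            starts >= 1)
  lo <- factors$low; hi <- factors$high
  if (is.null(response_bounds)) {
    corners <- as.matrix(expand.grid(lapply(1:4, function(i) c(lo[i], hi[i]))))
    pr <- predict(model, corners)
    response_bounds <- range(pr)
  }
  L <- response_bounds[1]; H <- response_bounds[2]
  if (L >= H) stop("response bounds must satisfy L < H", call. = FALSE)
  desir <- function(x) {
    y <- predict(model, x)
    d <- if (goal == "maximize") (y - L) / (H - L) else (H - y) / (H - L)
    min(1, max(0, d))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sols <- lapply(seq_len(starts), function(k) {
    x0 <- lo + stats::runif(4) * (hi - lo)
    opt <- stats::optim(x0, function(x) -desir(x), method = "L-BFGS-B",
                        lower = lo, upper = hi)
    list(levels = opt$par, desirability = -opt$value)
  })
  tab <- do.call(rbind, lapply(sols, function(s) {
    data.frame(N = s$levels[1], T = s$levels[2], U.A = s$levels[3],
               L.A = s$levels[4],
               response = predict(model, s$levels),
               desirability = s$desirability)
  }))
  key <- apply(round(tab[, 1:4], 4), 1, paste, collapse = ",")
  tab <- tab[!duplicated(key), ]
  tab <- tab[order(-tab$desirability, tab$response), ]
  rownames(tab) <- NULL
  structure(list(solutions = tab, goal = goal,
                 response_bounds = c(L = L, H = H)),
            class = "reba_optimization")
}

#' @export
print.reba_optimization <- function(x, ...) {
  cat(sprintf("<reba_optimization> goal: %s, %d unique solution(s)\n",
              x$goal, nrow(x$solutions)))
  print(utils::head(x$solutions, 3))
  invisible(x)
}
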
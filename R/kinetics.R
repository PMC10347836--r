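#' Piecewise-linear interpolation of a translation trajectory
#'
#' Ribosome-protected-fragment (RPF) abundance is measured only at stage
#' time points; the kinetic model needs a continuous translation input
#' r(t). Between consecutive nodes (t_k, t_{k+1}) the trajectory is
#' interpolated linearly, so it is exact at the nodes.
#'
#' @param times Strictly increasing numeric node times (>= 2 nodes).
#' @param values Nonnegative RPF values at the nodes.
#' @param t Times at which to evaluate; must lie within `range(times)`.
#' @return Numeric vector of interpolated values, one per element of `t`.
#' @examples
#' interpolate_rpf(0:2, c(1, 3, 2), c(0.5, 1.5))
#' @export
interpolate_rpf <- function(times, values, t) {
  check_trajectory(times, values)
  if (any(t < times[1] | t > times[length(times)])) {
    stop("interpolation time outside the trajectory range", call. = FALSE)
  }
  stats::approx(times, values, xout = t, method = "linear")$y
}

check_trajectory <- function(times, values) {
  if (length(times) < 2) stop("need at least two time points", call. = FALSE)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("node times must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("RPF values must be nonnegative", call. = FALSE)
  invisible(TRUE)
}

#' Simulate protein abundance under the mass-action kinetic model
#'
#' Solves dp/dt = alpha * r(t) - kd * p(t), where r(t) is the
#' piecewise-linear translation input, alpha converts translation signal to
#' protein synthesis, and kd is a first-order degradation rate assumed
#' constant across development. On each linear segment of r(t) the solution
#' is computed in closed form with the integrating factor, so the result is
#' exact up to floating point (a series expansion takes over where
#' `kd * dt` is tiny to avoid cancellation).
#'
#' @param p0 Initial protein abundance (linear scale) at `times[1]`.
#' @param alpha Synthesis constant (>= 0).
#' @param kd Degradation rate (>= 0), per unit of the time axis.
#' @param times,values Nodes of the RPF trajectory (see
#'   [interpolate_rpf()]).
#' @param eval_times Times at which to report p(t); defaults to the nodes.
#' @return Numeric vector p(`eval_times`).
#' @examples
#' # pure decay: r = 0 everywhere
#' simulate_protein(100, alpha = 0, kd = 0.5, times = 0:6, values = rep(0, 7))
#' @export
simulate_protein <- function(p0, alpha, kd, times, values, eval_times = times) {
  check_trajectory(times, values)
  if (p0 < 0 || alpha < 0 || kd < 0) {
    stop("p0, alpha and kd must be nonnegative", call. = FALSE)
  }
  if (any(eval_times < times[1] | eval_times > times[length(times)])) {
    stop("evaluation time outside the trajectory range", call. = FALSE)
  }
  ord <- order(eval_times)
  et <- eval_times[ord]
  out <- numeric(length(et))
  p_seg <- p0 # protein level at the start of the current segment
  j <- 1
  for (k in seq_len(length(times) - 1)) {
    t0 <- times[k]
    t1 <- times[k + 1]
    a <- values[k]
    b <- (values[k + 1] - values[k]) / (t1 - t0)
    while (j <= length(et) && (et[j] <= t1 || k == length(times) - 1)) {
      s <- et[j] - t0
      out[j] <- kinetic_step(p_seg, alpha, kd, a, b, s)
      j <- j + 1
    }
    p_seg <- kinetic_step(p_seg, alpha, kd, a, b, t1 - t0)
  }
  out[order(ord)] <- out
  out
}

# closed-form advance of the linear ODE by s within one segment where
# r(t0 + u) = a + b u:
#   p(t0+s) = p_seg e^{-kd s} + alpha (a J1 + b J2)
#   J1 = (1 - e^{-kd s})/kd,  J2 = (s - J1)/kd
kinetic_step <- function(p_seg, alpha, kd, a, b, s) {
  if (s == 0) return(p_seg)
  x <- kd * s
  if (x < 1e-4) {
    # series in x to avoid cancellation; relative truncation error O(x^4)
    j1 <- s * (1 - x / 2 + x^2 / 6 - x^3 / 24)
    j2 <- s^2 / 2 * (1 - x / 3 + x^2 / 12 - x^3 / 60)
    decay <- exp(-x)
  } else {
    decay <- exp(-x)
    j1 <- -expm1(-x) / kd
    j2 <- (s - j1) / kd
  }
  p_seg * decay + alpha * (a * j1 + b * j2)
}

#' Fit the kinetic model to one observed protein trajectory
#'
#' Infers per-gene synthesis (`alpha`) and degradation (`kd`) constants by
#' minimizing the sum of squared differences between observed linear-scale
#' protein abundances and the model prediction at observed time points,
#' subject to alpha, kd >= 0. Two variants are supported: `"p0_rpf"` takes
#' the observed first-stage (FGO) protein level as the initial condition
#' p0; `"rpf_only"` sets p0 = 0, so the prediction reflects synthesis and
#' degradation alone.
#'
#' The minimization is deterministic and exploits the structure of the
#' model: p(t | p0, alpha, kd) is linear in alpha by superposition, so for
#' any fixed kd the optimal nonnegative alpha has a closed form (variable
#' projection). The profiled objective is scanned over a dense log-spaced
#' kd grid scaled to the time axis, the best bracket is refined with
#' Brent's method, and a final bounded L-BFGS-B polish runs on (alpha, kd)
#' jointly. Missing observations are dropped from the objective, not
#' imputed.
#'
#' @param observed Linear-scale protein abundances at `times` (`NA` =
#'   not detected; at least 3 detected stages required).
#' @param times,values RPF trajectory nodes (same time axis as `observed`).
#' @param mode `"p0_rpf"` or `"rpf_only"`.
#' @param grid_n Number of nonzero points in the kd scan grid.
#' @param upper_scale Upper bound for each parameter, as a multiple of its
#'   data-derived scale. Fits ending within 1e-6 of a bound are flagged.
#' @return A one-row tibble: `p0`, `alpha`, `kd`, `sse`, `convergence`,
#'   `boundary` plus a `predicted` list-column with p(t) at `times`.
#' @export
fit_kinetic_model <- function(observed, times, values,
                              mode = c("p0_rpf", "rpf_only"),
                              grid_n = 40, upper_scale = 1e6) {
  mode <- match.arg(mode)
  check_trajectory(times, values)
  obs_idx <- which(!is.na(observed))
  if (length(obs_idx) < 3) {
    stop("need at least 3 observed stages to fit", call. = FALSE)
  }
  p0 <- if (mode == "p0_rpf") {
    if (is.na(observed[1])) {
      stop("p0_rpf mode requires a detected first-stage observation",
        call. = FALSE
      )
    }
    observed[1]
  } else {
    0
  }
  t_obs <- times[obs_idx]
  p_obs <- observed[obs_idx]
  t_range <- times[length(times)] - times[1]
  kd_ref <- 1 / t_range
  r_scale <- max(values, .Machine$double.eps)
  p_scale <- max(max(p_obs), .Machine$double.eps)
  alpha_upper <- p_scale / (r_scale * t_range) * upper_scale
  kd_upper <- kd_ref * upper_scale

  # profile out alpha: pred = decay + alpha * synth, both computable once
  # per kd; optimal alpha is a clamped least-squares coefficient
  profile_at <- function(kd) {
    decay <- simulate_protein(p0, 0, kd, times, values, t_obs)
    synth <- simulate_protein(0, 1, kd, times, values, t_obs)
    ss <- sum(synth^2)
    alpha <- if (ss > 0) sum(synth * (p_obs - decay)) / ss else 0
    alpha <- min(max(alpha, 0), alpha_upper)
    list(alpha = alpha, sse = sum((decay + alpha * synth - p_obs)^2))
  }
  kd_grid <- c(0, kd_ref * 10^seq(-4, 4, length.out = grid_n))
  kd_grid <- kd_grid[kd_grid <= kd_upper]
  prof <- lapply(kd_grid, profile_at)
  sse_grid <- vapply(prof, `[[`, 0, "sse")
  i_best <- which.min(sse_grid)
  kd_best <- kd_grid[i_best]
  alpha_best <- prof[[i_best]]$alpha
  sse_best <- sse_grid[i_best]

  # Brent-refine every local minimum of the scan (the profiled objective
  # can have several basins; the deepest one is not always the scan's
  # global minimum when a basin is narrower than the grid spacing)
  n_grid <- length(kd_grid)
  is_local_min <- vapply(seq_len(n_grid), function(i) {
    (i == 1 || sse_grid[i] <= sse_grid[i - 1]) &&
      (i == n_grid || sse_grid[i] <= sse_grid[i + 1])
  }, TRUE)
  for (i in which(is_local_min)) {
    lo <- kd_grid[max(i - 1, 1)]
    hi <- kd_grid[min(i + 1, n_grid)]
    if (hi <= lo) next
    opt <- stats::optimize(function(kd) profile_at(kd)$sse,
      interval = c(lo, hi), tol = .Machine$double.eps^0.5 * max(hi, kd_ref)
    )
    if (opt$objective < sse_best) {
      kd_best <- opt$minimum
      alpha_best <- profile_at(kd_best)$alpha
      sse_best <- opt$objective
    }
  }

  # joint bounded quasi-Newton polish on (alpha, kd)
  objective2 <- function(par) {
    pred <- simulate_protein(p0, par[1], par[2], times, values, t_obs)
    sum((pred - p_obs)^2)
  }
  convergence <- 0L
  polish <- tryCatch(
    stats::optim(c(alpha_best, kd_best), objective2,
      method = "L-BFGS-B", lower = c(0, 0),
      upper = c(alpha_upper, kd_upper),
      control = list(
        factr = 10,
        parscale = pmax(c(alpha_best, kd_best), c(alpha_upper, kd_upper) * 1e-9)
      )
    ),
    error = function(e) NULL
  )
  if (!is.null(polish) && is.finite(polish$value) && polish$value <= sse_best) {
    alpha_best <- polish$par[1]
    kd_best <- polish$par[2]
    sse_best <- polish$value
    convergence <- as.integer(polish$convergence)
  }
  tibble::tibble(
    p0 = p0,
    alpha = alpha_best,
    kd = kd_best,
    sse = sse_best,
    convergence = convergence,
    boundary = alpha_best >= alpha_upper * (1 - 1e-6) |
      kd_best >= kd_upper * (1 - 1e-6),
    predicted = list(
      simulate_protein(p0, alpha_best, kd_best, times, values, times)
    )
  )
}

#' Fit the kinetic model across a gene universe
#'
#' Data-frame front end to [fit_kinetic_model()]. Protein input is the
#' stage-averaged log2 matrix (converted internally to linear scale, 2^x);
#' RPF input is the stage-averaged FPKM matrix. Genes with fewer than 3
#' detected protein stages, or (in `"p0_rpf"` mode) without a detected
#' first-stage value, are skipped and counted in the `"n_skipped"`
#' attribute.
#'
#' @param protein Stage-averaged long tibble (`gene_id`, `stage`, `value`,
#'   log2 scale, `NA` = not detected).
#' @param rpf Stage-averaged long tibble of RPF FPKM.
#' @param mode Model variant, see [fit_kinetic_model()].
#' @param times Named stage time coordinates (see [oet_stage_times()]).
#' @param ... Passed on to [fit_kinetic_model()].
#' @return A tibble of class `"kinetic_fits"`: one row per fitted gene with
#'   `gene_id`, `mode`, `p0`, `alpha`, `kd`, `sse`, `boundary`,
#'   `r_pred_obs` (Spearman correlation between predicted and observed
#'   protein over detected stages) and the `predicted` list-column.
#' @seealso [evaluate_predictions()], [tidy.kinetic_fits()],
#'   [glance.kinetic_fits()]
#' @export
fit_kinetics <- function(protein, rpf, mode = c("p0_rpf", "rpf_only"),
                         times = oet_stage_times(), ...) {
  mode <- match.arg(mode)
  stages <- names(times)
  pw <- stage_value_matrix(protein, stages)
  rw <- stage_value_matrix(rpf, stages)
  genes <- intersect(rownames(pw), rownames(rw))
  if (length(genes) == 0) stop("no shared genes", call. = FALSE)
  skipped <- 0L
  rows <- lapply(genes, function(g) {
    obs_log2 <- pw[g, ]
    obs <- 2^obs_log2 # NA stays NA
    r <- rw[g, ]
    if (anyNA(r)) r[is.na(r)] <- 0
    ok <- sum(!is.na(obs)) >= 3 && (mode == "rpf_only" || !is.na(obs[1]))
    if (!ok) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    fit <- fit_kinetic_model(obs, unname(times), unname(r), mode = mode, ...)
    det <- !is.na(obs)
    r_po <- if (stats::sd(fit$predicted[[1]][det]) == 0 ||
      stats::sd(obs[det]) == 0) {
      NA_real_
    } else {
      stats::cor(fit$predicted[[1]][det], obs[det], method = "spearman")
    }
    dplyr::bind_cols(tibble::tibble(gene_id = g, mode = mode), fit,
      tibble::tibble(r_pred_obs = r_po)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_skipped") <- skipped
  attr(out, "times") <- times
  class(out) <- c("kinetic_fits", class(out))
  out
}

#' Summarize predicted-versus-observed protein concordance
#'
#' For one or more sets of kinetic fits, computes the per-mode median
#' Spearman correlation between predicted and observed protein
#' trajectories, alongside the raw protein-RPF gene-wise correlation as a
#' baseline if supplied.
#'
#' @param ... One or more `"kinetic_fits"` tibbles (e.g. the `"p0_rpf"`
#'   and `"rpf_only"` fits of the same universe).
#' @param baseline Optional result of [genewise_correlation()] to report as
#'   the `protein_rpf` row.
#' @return A tibble with columns `mode`, `n`, `n_undefined` (genes whose
#'   predicted series was constant so the correlation is undefined) and
#'   `median_r`.
#' @export
evaluate_predictions <- function(..., baseline = NULL) {
  fits <- list(...)
  rows <- lapply(fits, function(f) {
    tibble::tibble(
      mode = f$mode[1],
      n = sum(!is.na(f$r_pred_obs)),
      n_undefined = sum(is.na(f$r_pred_obs)),
      median_r = stats::median(f$r_pred_obs, na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(baseline)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      mode = "protein_rpf",
      n = sum(!is.na(baseline$r)),
      n_undefined = sum(is.na(baseline$r)),
      median_r = stats::median(baseline$r, na.rm = TRUE)
    ))
  }
  out
}

# internal: long stage-averaged tibble -> gene x stage matrix in stage order
stage_value_matrix <- function(x, stages) {
  wide <- x |>
    dplyr::mutate(stage = as.character(.data$stage)) |>
    dplyr::select("gene_id", "stage", "value") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "value")
  missing_stages <- setdiff(stages, names(wide))
  if (length(missing_stages) > 0) {
    stop("stages absent from matrix: ", paste(missing_stages, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(wide[, stages])
  rownames(m) <- wide$gene_id
  m
}
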
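#' TM-score between a model and a reference
#'
#' Length-normalised structural similarity in (0, 1]:
#' TM = (1 / L) * sum_i 1 / (1 + (d_i / d0)^2) over C-alpha pairs, with
#' d0 = 1.24 (L - 15)^(1/3) - 1.8 floored at 0.5 for short chains. The
#' residue correspondence is the identity (same protein, shared roster),
#' so no alignment search is needed; the superposition is refined
#' iteratively: start from the all-C-alpha least-squares fit, keep
#' residues with d_i < max(d0, 3 A), re-fit on those, and repeat until
#' the kept set is stable (at most 10 rounds). The best TM over the
#' refinement is returned.
#'
#' @param model full-roster coordinate matrix or `pse_structure`.
#' @param ref reference `pse_structure`.
#' @return TM-score in (0, 1]
#' @export
tm_score <- function(model, ref) {
  if (inherits(model, "pse_structure")) model <- coords(model)
  cas <- ca_indices(ref)
  L <- length(cas)
  if (L < 3) stop("TM-score needs at least 3 residues")
  d0 <- max(0.5, 1.24 * max(L - 15, 0)^(1 / 3) - 1.8)
  mob <- model[cas, , drop = FALSE]
  refc <- coords(ref)[cas, , drop = FALSE]
  tm_of <- function(m) mean(1 / (1 + (sqrt(rowSums((m - refc)^2)) / d0)^2))
  fit <- kabsch_superpose(mob, refc)
  best <- tm_of(fit$coords)
  kept_prev <- seq_len(L)
  cur <- fit$coords
  for (it in 1:10) {
    d <- sqrt(rowSums((cur - refc)^2))
    kept <- which(d < max(d0, 3))
    if (length(kept) < 3) break
    if (identical(kept, kept_prev)) break
    cur <- kabsch_superpose(mob, refc, kept)$coords
    best <- max(best, tm_of(cur))
    kept_prev <- kept
  }
  best
}

#' Ensemble spread fraction F
#'
#' The fraction of ensemble structures S with TM(S, A) > TM(B, A) and
#' TM(S, B) > TM(A, B): the proportion of models strictly closer to both
#' input structures than the inputs are to each other. F near 0.9 marks
#' an ensemble that effectively covers the conformational space between
#' the inputs; the auto-parameterisation targets it.
#'
#' @param e a nonempty `pse_ensemble` on the inputs' roster.
#' @param a,b the two input `pse_structure` objects.
#' @return list of class `spread_report` with `f`, `n_structures`,
#'   `tm_ab`, `tm_ba`, `per_model` (logical vector), `wb` (NA here;
#'   filled by [select_wb]).
#' @export
spread_fraction <- function(e, a, b) {
  if (!inherits(e, "pse_ensemble") || n_models(e) == 0) {
    stop("spread fraction needs a nonempty ensemble")
  }
  tm_ba <- tm_score(b, a)  # TM(B, A): B as model, A as reference
  tm_ab <- tm_score(a, b)
  hit <- vapply(e$models, function(m) {
    tm_score(m, a) > tm_ba && tm_score(m, b) > tm_ab
  }, logical(1))
  structure(list(f = mean(hit), n_structures = n_models(e),
                 tm_ab = tm_ab, tm_ba = tm_ba, per_model = hit,
                 wb = NA_real_),
            class = "spread_report")
}

#' Automatic tolerance-weight selection
#'
#' Ensembles of `n` structures are generated with the tolerance weight
#' starting at 1.0 and decreasing in steps of 0.1; the first weight
#' whose ensemble has spread fraction F >= `f_target` is chosen. Weight
#' 0 gives a narrow band of structures midway between the inputs; 1
#' gives a wide spread beyond them. If no weight reaches the target,
#' 0.0 is returned with a warning.
#'
#' @param a,b intersected input structures with secondary structure
#'   assigned.
#' @param f_target spread-fraction target (default 0.9).
#' @param n structures per trial ensemble (default 50).
#' @param params an [spe_params]; its master seed drives the whole search.
#' @return list with `wb` (chosen weight), `trace` (data frame of wb, f),
#'   `ensemble` (the ensemble generated at the chosen weight),
#'   `constraints` (its constraint set).
#' @export
select_wb <- function(a, b, f_target = 0.9, n = 50, params = spe_params()) {
  schedule <- seq(1.0, 0.0, by = -0.1)
  trace <- data.frame(wb = numeric(0), f = numeric(0))
  last <- NULL
  for (k in seq_along(schedule)) {
    wb <- schedule[k]
    cs <- build_constraint_set(a, b, wb, seed = derive_seed(params$seed, 900 + k))
    pk <- params
    pk$seed <- derive_seed(params$seed, 1000 * k)
    e <- generate_ensemble(cs, n, a, pk)
    rep <- spread_fraction(e, a, b)
    trace <- rbind(trace, data.frame(wb = wb, f = rep$f))
    last <- list(wb = wb, trace = trace, ensemble = e, constraints = cs,
                 f = rep$f)
    if (rep$f >= f_target) return(last)
  }
  warning("no tolerance weight reached the target spread fraction; using 0.0")
  last
}
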
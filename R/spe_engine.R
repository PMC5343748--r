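#' Embedding parameters
#'
#' `iterations_per_atom` is the product of the annealing cycle count C
#' and the steps per cycle S; the S:C ratio is fixed at 50 (any S > C
#' behaves similarly) so C = ceiling(sqrt(iterations_per_atom / 50)) and
#' S = 50 C. Each step performs one random-constraint update per atom on
#' average, so total work scales linearly with system size. The learning
#' rate decays linearly from `lambda_start` to `lambda_end` across
#' cycles, making the minimisation similar to simulated annealing.
#'
#' @param iterations_per_atom total C * S budget (default 60000, past
#'   which the error score stops improving).
#' @param s_to_c_ratio ratio S : C (default 50).
#' @param lambda_start,lambda_end learning-rate schedule endpoints.
#' @param discard_ratio embeddings generated per retained structure
#'   (default 1.5; the extra high-error structures are discarded).
#' @param seed master RNG seed.
#' @return list of class `spe_params`
#' @export
spe_params <- function(iterations_per_atom = 60000, s_to_c_ratio = 50,
                       lambda_start = 2.0, lambda_end = 0.1,
                       discard_ratio = 1.5, seed = 1L) {
  stopifnot(iterations_per_atom > 0, lambda_start >= lambda_end,
            lambda_end > 0, discard_ratio >= 1)
  cycles <- as.integer(ceiling(sqrt(iterations_per_atom / s_to_c_ratio)))
  steps <- as.integer(s_to_c_ratio * cycles)
  structure(list(iterations_per_atom = iterations_per_atom,
                 cycles = cycles, steps = steps,
                 lambda_start = lambda_start, lambda_end = lambda_end,
                 discard_ratio = discard_ratio, seed = seed),
            class = "spe_params")
}

#' Derived per-stream seed
#'
#' Master seed times 1e6 plus a stream index, wrapped into 32 bits; used
#' for every independent RNG stream of a run.
#' @param master master seed
#' @param index stream index
#' @return numeric seed
#' @export
derive_seed <- function(master, index) {
  (as.numeric(master) * 1e6 + as.numeric(index)) %% 2^31
}

#' Embed one structure against a constraint set
#'
#' Stochastic proximity embedding: coordinates are initialised uniformly
#' in a cube whose side scales with the cube root of the atom count
#' (roughly protein packing density) and refined by violation-driven
#' pair updates under a decaying learning rate. Deterministic given
#' `params$seed`.
#'
#' @param cs a [pse_constraint_set]
#' @param params an [spe_params] object
#' @return list with `coords` (n_atoms x 3), `error_score`, `mirrored`
#'   (FALSE here; see [fix_chirality]).
#' @export
spe_embed <- function(cs, params = spe_params()) {
  df <- cs$df
  box <- (cs$n_atoms)^(1 / 3) * 3
  xyz <- spe_embed_cpp(as.integer(df$i - 1L), as.integer(df$j - 1L),
                       df$lower, df$upper, cs$n_atoms,
                       params$cycles, params$steps, cs$n_atoms,
                       params$lambda_start, params$lambda_end,
                       box, params$seed)
  list(coords = xyz, error_score = error_score(xyz, cs), mirrored = FALSE)
}

#' Constraint-violation error score
#'
#' Sum of squared violations over all constraints: v = max(0, l - d,
#' d - u) per constraint, score = sum(v^2). Zero iff every constraint is
#' satisfied. High scores flag structures with poor stereochemistry,
#' which is why the worst embeddings of a batch are discarded.
#'
#' @param xyz n_atoms x 3 coordinate matrix
#' @param cs a [pse_constraint_set]
#' @return non-negative scalar
#' @export
error_score <- function(xyz, cs) {
  df <- cs$df
  error_score_cpp(xyz, as.integer(df$i - 1L), as.integer(df$j - 1L),
                  df$lower, df$upper)
}

#' Fix mirror-image embeddings
#'
#' Distance constraints carry no chirality, so half of all embeddings
#' come out as the mirror image. The optimal orthogonal superposition of
#' the embedding onto the reference is computed allowing reflection; if
#' the best transform is improper (determinant -1) the coordinates are
#' mirrored in the xy plane and flagged.
#'
#' @param xyz coordinate matrix (protein atoms, same roster as reference)
#' @param reference a `pse_structure` sharing the roster
#' @return list with `coords`, `mirrored`
#' @export
fix_chirality <- function(xyz, reference) {
  ref <- coords(reference)
  n <- nrow(ref)
  stopifnot(nrow(xyz) >= n)
  p <- sweep(xyz[seq_len(n), , drop = FALSE], 2,
             colMeans(xyz[seq_len(n), , drop = FALSE]))
  q <- sweep(ref, 2, colMeans(ref))
  sv <- svd(crossprod(p, q))
  if (det(sv$u %*% t(sv$v)) < 0) {
    out <- xyz
    out[, 3] <- -out[, 3]
    list(coords = out, mirrored = TRUE)
  } else {
    list(coords = xyz, mirrored = FALSE)
  }
}

#' Generate an ensemble of embedded structures
#'
#' Runs `ceiling(discard_ratio * n)` embeddings with per-structure seeds
#' derived from the master seed, fixes chirality against the reference,
#' and keeps the `n` structures with the lowest error score (seed order
#' within the kept set, for determinism). Constraint sets may contain
#' more points than the reference roster (modulator pseudo-atoms); only
#' the protein atoms are stored in the models.
#'
#' @param cs a [pse_constraint_set]
#' @param n number of structures to retain.
#' @param reference `pse_structure` supplying the roster and chirality.
#' @param params an [spe_params]
#' @return a [pse_ensemble] with per-model error scores
#' @export
generate_ensemble <- function(cs, n, reference, params = spe_params()) {
  stopifnot(n >= 1)
  n_protein <- n_atoms(reference)
  stopifnot(cs$n_atoms >= n_protein)
  n_total <- as.integer(ceiling(params$discard_ratio * n))
  models <- vector("list", n_total)
  scores <- numeric(n_total)
  for (k in seq_len(n_total)) {
    pk <- params
    pk$seed <- derive_seed(params$seed, k)
    res <- spe_embed(cs, pk)
    fx <- fix_chirality(res$coords, reference)
    models[[k]] <- fx$coords[seq_len(n_protein), , drop = FALSE]
    scores[k] <- res$error_score
  }
  keep <- sort(order(scores)[seq_len(n)])
  e <- pse_ensemble(reference$atoms, models[keep], error_scores = scores[keep])
  attr(e, "n_attempted") <- n_total
  attr(e, "discarded_scores") <- scores[-keep]
  e
}

#' Write per-model error scores as TSV
#' @param e a `pse_ensemble`
#' @param path output path
#' @return path, invisibly
#' @export
write_error_scores <- function(e, path) {
  write.table(data.frame(model = seq_len(n_models(e)),
                         error_score = e$error_scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
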
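#' Run configuration
#'
#' Bundles input paths, ensemble size, tolerance-weight policy and the
#' master seed that governs every RNG stream of a run, so reruns with
#' the same config are bit-for-bit reproducible.
#'
#' @param structure_a,structure_b PDB paths (b = NULL for the
#'   single-structure perturbation workflow).
#' @param dssp_a,dssp_b optional DSSP files; without them the torsion
#'   fallback assigns secondary structure.
#' @param pockets optional pocket TSV path (x, y, z, pocket_id, volume).
#' @param n_models ensemble size (default 250).
#' @param wb `"auto"` (select via spread fraction) or a fixed value in
#'   \[0, 1\].
#' @param f_target spread-fraction target for auto selection (default 0.9).
#' @param spe list of [spe_params] overrides.
#' @param seed master seed (default 1).
#' @param out_dir output directory.
#' @return list of class `pse_config`
#' @export
pse_config <- function(structure_a, structure_b = NULL, dssp_a = NULL,
                       dssp_b = NULL, pockets = NULL, n_models = 250,
                       wb = "auto", f_target = 0.9, spe = list(),
                       seed = 1L, out_dir = ".") {
  stopifnot(n_models >= 1, f_target >= 0, f_target <= 1)
  if (!identical(wb, "auto")) stopifnot(is.numeric(wb), wb >= 0, wb <= 1)
  structure(list(structure_a = structure_a, structure_b = structure_b,
                 dssp_a = dssp_a, dssp_b = dssp_b, pockets = pockets,
                 n_models = n_models, wb = wb, f_target = f_target,
                 spe = spe, seed = seed, out_dir = out_dir),
            class = "pse_config")
}

#' Read a run configuration from a key=value file
#'
#' Plain-text config: one `key = value` per line, `#` comments allowed.
#' Recognised keys are the arguments of [pse_config] plus the embedding
#' keys `iterations_per_atom`, `lambda_start`, `lambda_end`,
#' `discard_ratio`. Arguments passed directly override file values.
#'
#' @param path config file path.
#' @param ... overrides forwarded to [pse_config].
#' @return a [pse_config]
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  conv <- function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  kv <- setNames(lapply(vals, conv), keys)
  spe_keys <- intersect(names(kv), c("iterations_per_atom", "lambda_start",
                                     "lambda_end", "discard_ratio"))
  cfg_args <- kv[setdiff(names(kv), spe_keys)]
  cfg_args$spe <- kv[spe_keys]
  over <- list(...)
  cfg_args[names(over)] <- over
  bad <- setdiff(names(cfg_args), names(formals(pse_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pse_config, cfg_args)
}

config_params <- function(cfg) {
  p <- do.call(spe_params, c(cfg$spe, list(seed = cfg$seed)))
  p
}

prepare_inputs <- function(cfg) {
  a <- strip_non_protein(read_structure(cfg$structure_a))
  if (is.null(cfg$structure_b)) {
    b <- a
  } else {
    b <- strip_non_protein(read_structure(cfg$structure_b))
  }
  both <- intersect_atoms(a, b)
  a <- assign_secondary_structure(both$a, cfg$dssp_a)
  b <- assign_secondary_structure(both$b, cfg$dssp_b)
  list(a = a, b = b)
}

resolve_wb <- function(cfg, a, b, params) {
  if (identical(cfg$wb, "auto")) {
    sel <- select_wb(a, b, f_target = cfg$f_target, n = 50, params = params)
    list(wb = sel$wb, trace = sel$trace, cs = sel$constraints)
  } else {
    cs <- build_constraint_set(a, b, cfg$wb, seed = derive_seed(cfg$seed, 900))
    list(wb = cfg$wb, trace = NULL, cs = cs)
  }
}

write_manifest <- function(cfg, extra, path) {
  flat <- function(x) if (is.null(x)) "NULL" else paste(format(x), collapse = ",")
  kv <- c(vapply(cfg[!vapply(cfg, is.list, logical(1))], flat, character(1)),
          spe = flat(unlist(cfg$spe)), extra,
          package_version = as.character(utils::packageVersion("protsemble")),
          r_version = R.version.string)
  writeLines(sprintf("%s\t%s", names(kv), kv), path)
  invisible(path)
}

#' End-to-end ensemble generation
#'
#' Reads and cleans the two structures, intersects rosters, assigns
#' secondary structure, selects (or takes) the tolerance weight, builds
#' the combined constraint set, generates and aligns the ensemble, runs
#' PCA, and writes constraint/ensemble/score/PCA tables plus a manifest
#' into the output directory.
#'
#' @param cfg a [pse_config]
#' @return list with `ensemble`, `constraints`, `wb`, `trace`, `pca`
#'   (invisibly)
#' @export
run_generate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  inp <- prepare_inputs(cfg)
  sel <- resolve_wb(cfg, inp$a, inp$b, params)
  message(sprintf("generate: %d atoms, wb=%.1f, %d constraints",
                  n_atoms(inp$a), sel$wb, nrow(sel$cs$df)))
  e <- generate_ensemble(sel$cs, cfg$n_models, inp$a, params)
  e <- iterative_align(e)
  pc <- pca_ensemble(e)
  op <- function(f) file.path(cfg$out_dir, f)
  write_constraints(sel$cs, op("constraints.tsv"))
  write_ensemble(e, op("ensemble.pdb"))
  write_error_scores(e, op("error_scores.tsv"))
  write.table(data.frame(component = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues,
                         variance_fraction = pc$variance_fractions),
              op("pca_eigenvalues.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  proj <- t(vapply(e$models, function(m) {
    vapply(1:min(3, length(pc$eigenvalues)),
           function(k) project_onto_pc(m, pc, k), numeric(1))
  }, numeric(min(3, length(pc$eigenvalues)))))
  write.table(data.frame(model = seq_len(n_models(e)), proj),
              op("pca_projections.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sel$trace)) {
    write.table(sel$trace, op("wb_trace.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_manifest(cfg, c(chosen_wb = format(sel$wb)), op("manifest.tsv"))
  invisible(list(ensemble = e, constraints = sel$cs, wb = sel$wb,
                 trace = sel$trace, pca = pc, inputs = inp))
}

#' End-to-end allosteric pocket ranking
#'
#' Generates the unperturbed ensemble, perturbs each supplied pocket
#' with simulated-modulator constraints, ranks pockets by the shift of
#' the ensemble average, and writes a ranking report. When modulator
#' atoms are supplied the 6 Angstrom validation criterion and the
#' "allosteric pocket in the top 2" success flag are reported as well.
#'
#' @param cfg a [pse_config] with `pockets` set.
#' @param modulator_atoms optional m x 3 matrix of known-modulator atoms.
#' @param write_ensembles also write each pocket's perturbed ensemble as
#'   a multi-model PDB (default FALSE).
#' @return list with `ranking` (data frame), `perturbation`, `wb`
#'   (invisibly)
#' @export
run_allostery <- function(cfg, modulator_atoms = NULL,
                          write_ensembles = FALSE) {
  if (is.null(cfg$pockets)) stop("config has no pockets file")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  inp <- prepare_inputs(cfg)
  sel <- resolve_wb(cfg, inp$a, inp$b, params)
  pockets <- filter_pockets(read_pockets_tsv(cfg$pockets))
  op <- function(f) file.path(cfg$out_dir, f)
  if (length(pockets) == 0) {
    warning("no pockets pass the filter; writing empty report")
    writeLines("pocket_id\tvolume\tn_constraints\tshift_rmsd\trank",
               op("ranking.tsv"))
    return(invisible(list(ranking = NULL)))
  }
  pr <- perturb_and_rank(inp$a, inp$b, pockets, sel$cs,
                         n_models_per = cfg$n_models, params = params)
  tab <- ranking_table(pr)
  if (!is.null(modulator_atoms)) {
    allo <- vapply(pockets, function(p) {
      is_allosteric_pocket(p, modulator_atoms)
    }, logical(1))
    tab$allosteric <- allo[match(tab$pocket_id,
                                 vapply(pockets, function(p) p$id, integer(1)))]
    tab$top2_correct <- any(tab$allosteric[tab$rank <= 2])
  }
  write.table(tab, op("ranking.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (write_ensembles) {
    for (r in pr$results) {
      write_ensemble(r$perturbed_ensemble,
                     op(sprintf("perturbed_pocket_%d.pdb", r$pocket_id)))
    }
    write_ensemble(pr$unperturbed, op("unperturbed.pdb"))
  }
  write_manifest(cfg, c(chosen_wb = format(sel$wb)), op("manifest.tsv"))
  invisible(list(ranking = tab, perturbation = pr, wb = sel$wb,
                 inputs = inp, pockets = pockets))
}

#' Mean-square-fluctuation comparison of ensembles
#'
#' Computes per-residue MSF for each ensemble, MSF ratios against the
#' designated reference ensemble, and chain-wise C-alpha RMSD between
#' the average structures of every ensemble pair.
#'
#' @param cfg a [pse_config] (used for `out_dir`).
#' @param ensembles named list of at least two ensembles on one roster.
#' @param reference name or index of the reference ensemble (default 1).
#' @return list with `msf` (residues x ensembles), `ratios`,
#'   `chain_rmsd` (invisibly)
#' @export
run_msf <- function(cfg, ensembles, reference = 1) {
  stopifnot(length(ensembles) >= 2)
  rosters <- lapply(ensembles, function(e) paste(e$roster$name, e$roster$resseq))
  if (!all(vapply(rosters, identical, logical(1), rosters[[1]]))) {
    stop("ensembles have different rosters")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ensembles <- lapply(ensembles, function(e) {
    if (isTRUE(e$aligned)) e else iterative_align(e)
  })
  msf <- vapply(ensembles, rmsf, numeric(sum(ensembles[[1]]$roster$name == "CA")))
  ref <- ensembles[[reference]]
  ratios <- vapply(ensembles, function(e) rmsf_ratio(e, ref), numeric(nrow(msf)))
  # chain-wise average-structure RMSD per ensemble pair, in a pooled frame
  roster <- ensembles[[1]]$roster
  cas <- which(roster$name == "CA")
  chains <- unique(roster$chain)
  pairs <- utils::combn(length(ensembles), 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    pooled <- pse_ensemble(roster, c(ensembles[[i]]$models,
                                     ensembles[[j]]$models))
    pooled <- iterative_align(pooled)
    ni <- n_models(ensembles[[i]])
    ai <- Reduce(`+`, pooled$models[seq_len(ni)]) / ni
    aj <- Reduce(`+`, pooled$models[-seq_len(ni)]) /
      (n_models(pooled) - ni)
    for (ch in chains) {
      sub <- intersect(cas, which(roster$chain == ch))
      rows[[length(rows) + 1]] <- data.frame(
        ensemble_i = i, ensemble_j = j, chain = ch,
        rmsd = rmsd_plain(ai, aj, sub))
    }
  }
  chain_rmsd <- do.call(rbind, rows)
  op <- function(f) file.path(cfg$out_dir, f)
  write.table(cbind(residue = seq_len(nrow(msf)), as.data.frame(msf)),
              op("msf.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(residue = seq_len(nrow(ratios)), as.data.frame(ratios)),
              op("msf_ratios.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(chain_rmsd, op("chain_rmsd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(msf = msf, ratios = ratios, chain_rmsd = chain_rmsd))
}
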
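logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Jarzynski free-energy estimate from a work sample
#'
#' The exponential-work identity `exp(-dG/kT) = <exp(-W/kT)>` applied to
#' a finite sample: `dG = -kT * log(mean(exp(-W/kT)))`, evaluated with a
#' max-shifted log-sum-exp so that `|W|/kT` far beyond the floating-point
#' exponent range remains finite.  For a zero-variance sample the
#' estimate equals the common work value exactly; in general it is
#' bounded above by the sample mean (Jensen).
#'
#' @param work Numeric vector of work values, kcal/mol.
#' @param kT Thermal energy, kcal/mol (default 300 K).
#' @return Free-energy difference, kcal/mol.
#' @export
jarzynski_free_energy <- function(work, kT = kT_at(300)) {
  if (!length(work)) stop("empty work sample")
  stopifnot(is.numeric(work), kT > 0)
  -kT * (logsumexp(-work / kT) - log(length(work)))
}

#' Per-transition work samples from the energy grid
#'
#' In the quasi-static limit the work for moving between adjacent shells
#' reduces to the potential-energy difference between them.  In the
#' default `"replicate"` pairing each bound-state snapshot's lineage
#' provides one work sample per transition:
#' `W_j = U[j, near] - U[j, far]` taken in the binding (far -> near)
#' direction, so that favourable binding yields negative work.  The
#' `"ensemble"` mode does not pair replicates; it is consumed downstream
#' by [mrc_score()] as a ratio of per-shell Boltzmann sums.
#'
#' @param energies `conformation_set` or an n_replicates x n_shells
#'   energy matrix (kcal/mol).
#' @param transition Index i of the transition between shells i and i+1.
#' @param pairing_mode `"replicate"` or `"ensemble"`.
#' @param direction `"binding"` (default, far -> near) or `"unbinding"`.
#' @return Numeric vector of work values (one per replicate).
#' @export
shell_work_samples <- function(energies, transition,
                               pairing_mode = c("replicate", "ensemble"),
                               direction = c("binding", "unbinding")) {
  pairing_mode <- match.arg(pairing_mode)
  direction <- match.arg(direction)
  U <- if (inherits(energies, "conformation_set")) energies$energies
       else as.matrix(energies)
  if (anyNA(U)) stop("incomplete energy grid")
  if (transition < 1L || transition >= ncol(U))
    stop("transition index out of range")
  if (pairing_mode == "ensemble")
    stop("ensemble pairing has no per-replicate work samples; use mrc_score")
  w <- U[, transition] - U[, transition + 1L]
  if (direction == "unbinding") w <- -w
  w
}

#' MRC-MMGBSA score from the energy grid
#'
#' Aggregates the replicate-by-shell potential energies into per-
#' transition free-energy increments and their sum, the MRC-MMGBSA
#' score.  With the default `"replicate"` pairing each transition's
#' increment is the Jarzynski exponential average over the per-replicate
#' work samples; with `"ensemble"` pairing it is the log-ratio of the
#' shells' Boltzmann sums, `-kT * log(Z_near / Z_far)`.  Transitions are
#' taken in the binding direction by default, so a stronger binder has a
#' more negative total score.
#'
#' @inheritParams shell_work_samples
#' @param energies `conformation_set` or energy matrix.
#' @param schedule `r_schedule`; taken from the conformation set when
#'   omitted.
#' @param kT Thermal energy, kcal/mol.
#' @param jackknife Also compute leave-one-replicate-out standard errors.
#' @return A `score_result`: `shell_scores` (one per adjacent-shell
#'   transition), `total_score`, `kT`, `epsilon_in`, `pairing_mode`,
#'   `direction`, `n_replicates`, and optionally `shell_se`, `total_se`.
#' @export
mrc_score <- function(energies, schedule = NULL, kT = kT_at(300),
                      pairing_mode = c("replicate", "ensemble"),
                      direction = c("binding", "unbinding"),
                      jackknife = FALSE) {
  pairing_mode <- match.arg(pairing_mode)
  direction <- match.arg(direction)
  eps_in <- NA_real_
  if (inherits(energies, "conformation_set")) {
    if (is.null(schedule)) schedule <- energies$schedule
    eps_in <- energies$eps_in
    U <- energies$energies
  } else U <- as.matrix(energies)
  if (anyNA(U)) stop("incomplete energy grid")
  if (ncol(U) < 2L) stop("need at least 2 shells to score")
  if (!is.null(schedule) && length(schedule$distances) != ncol(U))
    stop("schedule length does not match the energy grid")
  n_tr <- ncol(U) - 1L
  score_one <- function(U) {
    vapply(seq_len(n_tr), function(i) {
      near <- i; far <- i + 1L
      if (direction == "unbinding") { near <- i + 1L; far <- i }
      if (pairing_mode == "replicate") {
        jarzynski_free_energy(U[, near] - U[, far], kT)
      } else {
        -kT * (logsumexp(-U[, near] / kT) - logsumexp(-U[, far] / kT))
      }
    }, numeric(1))
  }
  shell_scores <- score_one(U)
  out <- list(shell_scores = shell_scores, total_score = sum(shell_scores),
              kT = kT, epsilon_in = eps_in, pairing_mode = pairing_mode,
              direction = direction, n_replicates = nrow(U),
              schedule = schedule)
  if (jackknife && nrow(U) > 1L) {
    n <- nrow(U)
    jk <- t(vapply(seq_len(n),
                   function(j) score_one(U[-j, , drop = FALSE]),
                   numeric(n_tr)))
    if (n_tr == 1L) jk <- matrix(jk, ncol = 1L)
    out$shell_se <- sqrt((n - 1) / n * colSums(sweep(jk, 2, colMeans(jk))^2))
    tot <- rowSums(jk)
    out$total_se <- sqrt((n - 1) / n * sum((tot - mean(tot))^2))
  }
  structure(out, class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<MRC-MMGBSA score: total = %.4f kcal/mol over %d transitions (%s pairing, %s direction)>\n",
              x$total_score, length(x$shell_scores), x$pairing_mode,
              x$direction))
  invisible(x)
}

#' Single-structure MM-GBSA score
#'
#' The classical comparator: `G_complex - G_receptor - G_ligand`, each
#' term the final energy of an independent minimization of that species
#' in the implicit solvent model.  Set `minimize = FALSE` to evaluate the
#' input geometries directly.
#'
#' @param system A `complex_system`.
#' @param eps_in Interior dielectric constant.
#' @param engine Optional engine factory `function(molecules)`; defaults
#'   to [toy_engine()].
#' @param engine_args Extra arguments for [toy_engine()].
#' @param minimize Minimize each species before sampling its energy.
#' @param tol,switch_step,max_steps Minimizer settings (see
#'   [minimize_template()]).
#' @param use_apo_receptor Use the apo receptor conformation for the free-
#'   receptor term when the system provides one.
#' @return Score in kcal/mol with attribute `terms` holding the three
#'   species energies.
#' @export
s_mmgbsa_score <- function(system, eps_in = 1, engine = NULL,
                           engine_args = list(), minimize = TRUE,
                           tol = 0.1, switch_step = 100L, max_steps = 5000L,
                           use_apo_receptor = !is.null(system$receptor_apo)) {
  stopifnot(inherits(system, "complex_system"))
  make_engine <- if (is.null(engine))
    function(mols) do.call(toy_engine, c(list(mols, eps_in = eps_in), engine_args))
  else engine
  rec <- if (use_apo_receptor && !is.null(system$receptor_apo))
    system$receptor_apo else system$receptor
  species <- list(
    complex = list(list(system$receptor, system$ligand),
                   rbind(coords(system$receptor), coords(system$ligand))),
    receptor = list(list(rec), coords(rec)),
    ligand = list(list(system$ligand), coords(system$ligand)))
  g <- vapply(names(species), function(nm) {
    eng <- make_engine(species[[nm]][[1]])
    x <- species[[nm]][[2]]
    tryCatch({
      if (minimize)
        minimize_template(eng, x, tol = tol, switch_step = switch_step,
                          max_steps = max_steps)$final_energy
      else eng$energy(x)
    }, error = function(e)
      stop("energy failure on species '", nm, "': ", conditionMessage(e)))
  }, numeric(1))
  structure(unname(g["complex"] - g["receptor"] - g["ligand"]), terms = g)
}

#' Linear score-to-affinity scaling
#'
#' `dG_calc = alpha * score + beta`; the slope generalizes across
#' targets (about 0.20) while the intercept is system dependent.
#'
#' @param score MRC-MMGBSA (or S-MMGBSA) score, kcal/mol.
#' @param alpha Weighting factor.
#' @param beta Intercept, kcal/mol.
#' @return Calculated binding free energy, kcal/mol.
#' @export
linear_affinity <- function(score, alpha = 0.20, beta = 0) {
  alpha * score + beta
}

#' Relative binding free energies from scores
#'
#' Computes `ddG_calc(X) = alpha * (score_X - score_ref)` against a
#' reference ligand.  When experimental affinities are present the
#' reference is the ligand with the highest (least favourable) `dg_exp`;
#' ties are broken deterministically by ligand label order with a
#' warning.  Without affinities an explicit `reference` label is
#' required.
#'
#' @param table data.frame with columns `ligand`, `score` and optionally
#'   `dg_exp` (kcal/mol); ligand labels must be unique.
#' @param alpha Generalized weighting factor (default 0.20).
#' @param reference Optional explicit reference ligand label.
#' @return The table with a `ddg_calc` column and, when `dg_exp` is
#'   present, `ddg_exp`; the reference row has `ddg_calc = 0`.
#' @export
delta_delta_g <- function(table, alpha = 0.20, reference = NULL) {
  table <- as.data.frame(table)
  stopifnot(all(c("ligand", "score") %in% names(table)))
  if (nrow(table) < 2L) stop("need at least 2 ligands")
  if (anyDuplicated(table$ligand)) stop("ligand labels must be unique")
  if (is.null(reference)) {
    if (is.null(table$dg_exp))
      stop("configuration error: no dg_exp column and no explicit reference")
    top <- which(table$dg_exp == max(table$dg_exp))
    if (length(top) > 1L) {
      warning("ties in dg_exp; breaking deterministically by ligand label order")
      top <- top[order(table$ligand[top])][1L]
    }
    reference <- table$ligand[top]
  }
  if (!reference %in% table$ligand)
    stop("configuration error: reference ligand '", reference, "' not in table")
  s_ref <- table$score[table$ligand == reference]
  table$ddg_calc <- alpha * (table$score - s_ref)
  if (!is.null(table$dg_exp))
    table$ddg_exp <- table$dg_exp - table$dg_exp[table$ligand == reference]
  attr(table, "reference") <- reference
  table
}

#' Pearson correlation between scores and affinities
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero
#'   variance.
#' @return Sample Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input")
  stats::cor(x, y)
}
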
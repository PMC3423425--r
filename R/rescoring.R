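#' Docking pose set
#'
#' A ligand's reference complex (X-ray/NMR/model) together with one or
#' more docking poses of the same ligand against the same receptor.
#'
#' @param label Ligand label.
#' @param reference `complex_system` of the reference structure.
#' @param poses List of `complex_system` poses sharing the reference's
#'   ligand topology.
#' @param dg_exp Optional experimental binding free energy, kcal/mol.
#' @return A `pose_set`.
#' @export
pose_set <- function(label, reference, poses, dg_exp = NA_real_) {
  stopifnot(inherits(reference, "complex_system"), length(poses) >= 1L)
  for (p in poses) {
    stopifnot(inherits(p, "complex_system"))
    if (nrow(p$ligand$atoms) != nrow(reference$ligand$atoms))
      stop("pose ligand topology differs from the reference")
  }
  structure(list(label = label, reference = reference, poses = poses,
                 dg_exp = dg_exp), class = "pose_set")
}

#' Optimal-pose classification
#'
#' A docking pose counts as the optimal docking structure when the
#' ligand heavy-atom RMS displacement after receptor superposition is
#' strictly less than the cutoff (default 2.0 Angstrom).
#'
#' @param rmsd Ligand RMSD(s) after receptor fit, Angstrom.
#' @param cutoff Cutoff in Angstrom.
#' @return Logical vector.
#' @export
classify_optimal_pose <- function(rmsd, cutoff = 2.0) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  rmsd < cutoff
}

#' Rescore a set of docking poses
#'
#' Scores every pose with S-MMGBSA or MRC-MMGBSA, computes its ligand
#' RMSD to the reference after receptor superposition, flags optimal
#' poses, and ranks by score (more negative is better; ties broken by
#' pose index).  Poses whose scoring fails are excluded from the ranking
#' and reported with `failed = TRUE`.
#'
#' @param pose_set A `pose_set`.
#' @param method `"smmgbsa"` or `"mrc"`.
#' @param eps_in Interior dielectric constant.
#' @param cutoff Optimal-pose RMSD cutoff, Angstrom.
#' @param seed RNG seed (MRC scoring only).
#' @param smmgbsa_args Extra arguments for [s_mmgbsa_score()].
#' @param mrc_args Extra arguments for [generate_conformation_set()]
#'   (e.g. `n_conf`, `n_min`, `schedule`, `sampler`).
#' @return data.frame of class `pose_scores`: `pose`, `method`, `score`,
#'   `rmsd`, `is_optimal`, `failed`, `rank`, sorted best-first.
#' @export
rescore_poses <- function(pose_set, method = c("smmgbsa", "mrc"), eps_in = 1,
                          cutoff = 2.0, seed = 1L, smmgbsa_args = list(),
                          mrc_args = list()) {
  stopifnot(inherits(pose_set, "pose_set"))
  method <- match.arg(method)
  n <- length(pose_set$poses)
  score <- rmsd <- rep(NA_real_, n)
  failed <- logical(n)
  for (k in seq_len(n)) {
    p <- pose_set$poses[[k]]
    rmsd[k] <- ligand_rmsd_after_receptor_fit(pose_set$reference, p)
    s <- tryCatch({
      if (method == "smmgbsa") {
        do.call(s_mmgbsa_score, c(list(p, eps_in = eps_in), smmgbsa_args))
      } else {
        cs <- do.call(generate_conformation_set,
                      c(list(p, seed = substream_seed(seed, k, 0L),
                             eps_in = eps_in, store_conformations = FALSE),
                        mrc_args))
        mrc_score(cs)$total_score
      }
    }, error = function(e) {
      warning("pose ", k, " of '", pose_set$label, "' failed scoring: ",
              conditionMessage(e))
      NA_real_
    })
    if (is.na(s)) failed[k] <- TRUE else score[k] <- as.numeric(s)
  }
  out <- data.frame(ligand = pose_set$label, pose = seq_len(n),
                    method = method, score = score, rmsd = rmsd,
                    is_optimal = classify_optimal_pose(rmsd, cutoff),
                    failed = failed)
  ord <- order(failed, score, out$pose)
  out <- out[ord, ]
  out$rank <- NA_integer_
  out$rank[!out$failed] <- seq_len(sum(!out$failed))
  rownames(out) <- NULL
  class(out) <- c("pose_scores", "data.frame")
  out
}

#' Rank ligands by their top-scored docking pose
#'
#' For each ligand the best-scored pose's score enters the affinity
#' table; when at least three ligands carry experimental affinities the
#' Pearson correlation between top-pose scores and `dg_exp` is attached.
#'
#' @param pose_sets List of `pose_set` objects.
#' @param method,eps_in,cutoff,seed,smmgbsa_args,mrc_args As in
#'   [rescore_poses()].
#' @param affinities Optional data.frame `ligand`, `dg_exp` overriding
#'   per-set affinities.
#' @return data.frame with one row per ligand (`ligand`, `score`,
#'   `pose`, `rmsd`, `is_optimal`, `dg_exp`), with attributes
#'   `pearson_r` (or NA with a warning when too few affinities) and
#'   `pose_scores` (the per-pose detail).
#' @export
rank_ligands_by_top_pose <- function(pose_sets, method = c("smmgbsa", "mrc"),
                                     eps_in = 1, cutoff = 2.0, seed = 1L,
                                     smmgbsa_args = list(), mrc_args = list(),
                                     affinities = NULL) {
  method <- match.arg(method)
  detail <- lapply(pose_sets, rescore_poses, method = method, eps_in = eps_in,
                   cutoff = cutoff, seed = seed, smmgbsa_args = smmgbsa_args,
                   mrc_args = mrc_args)
  top <- do.call(rbind, lapply(detail, function(d) {
    ok <- d[!d$failed, , drop = FALSE]
    if (!nrow(ok)) stop("all poses failed for ligand '", d$ligand[1], "'")
    ok[1L, c("ligand", "score", "pose", "rmsd", "is_optimal")]
  }))
  dg <- vapply(pose_sets, function(ps) ps$dg_exp, numeric(1))
  if (!is.null(affinities))
    dg <- affinities$dg_exp[match(top$ligand, affinities$ligand)]
  top$dg_exp <- dg
  rownames(top) <- NULL
  r <- NA_real_
  have <- is.finite(top$dg_exp)
  if (sum(have) >= 3L) {
    r <- pearson_r(top$score[have], top$dg_exp[have])
  } else if (any(have) || !is.null(affinities)) {
    warning("fewer than 3 ligands with affinities; correlation omitted")
  }
  attr(top, "pearson_r") <- r
  attr(top, "pose_scores") <- do.call(rbind, detail)
  top
}
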
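# Synthetic longitudinal paired scTCR + phenotype (+ expression) cohorts
# with planted ground truth: heavy-tailed clonotype sizes, arm-dependent
# Treg proportions and clonotype persistence, phenotype-transition
# kernels, planted CDR3 motif families and DE genes, and QC defects.

# interior amino-acid frequencies (roughly natural aa abundances)
CDR3_AA_FREQ <- c(
  A = 0.074, C = 0.005, D = 0.043, E = 0.055, F = 0.037, G = 0.091,
  H = 0.021, I = 0.036, K = 0.042, L = 0.085, M = 0.018, N = 0.041,
  P = 0.046, Q = 0.051, R = 0.057, S = 0.102, T = 0.069, V = 0.052,
  W = 0.017, Y = 0.058)

TRAV_POOL <- paste0("TRAV", c(2:9, 12:30))
TRAJ_POOL <- paste0("TRAJ", c(3:17, 21:32, 34:45))
TRBV_POOL <- paste0("TRBV", c(2:30))
TRBJ_POOL <- paste0("TRBJ", c("1-1", "1-2", "1-3", "1-4", "1-5", "1-6",
                              "2-1", "2-2", "2-3", "2-4", "2-5", "2-6", "2-7"))

# Zipf-like usage over a gene pool
gene_probs <- function(pool) {
  p <- 1 / seq_along(pool)
  p / sum(p)
}

#' Sample naive-repertoire CDR3 amino-acid sequences
#'
#' Germline-like sequences: conserved "C" start, "F" (90%) or "W" end,
#' interior positions drawn independently from a fixed amino-acid
#' frequency table, lengths uniform-ish over `min_len:max_len` with a
#' central peak. Used both by the cohort generator and as the default
#' motif-mining background.
#'
#' @param n Number of sequences.
#' @param min_len,max_len CDR3 length range (default 10-20).
#' @return Character vector of length `n`.
#' @export
simulate_naive_cdr3 <- function(n, min_len = 10, max_len = 20) {
  lens <- min_len:max_len
  mid <- (min_len + max_len) / 2
  wl <- 1 / (1 + abs(lens - mid))
  len <- if (length(lens) == 1L) rep.int(lens, n)
         else sample(lens, n, replace = TRUE, prob = wl)
  vapply(len, function(L) {
    paste0("C",
           paste(sample(names(CDR3_AA_FREQ), L - 2L, replace = TRUE,
                        prob = CDR3_AA_FREQ), collapse = ""),
           sample(c("F", "W"), 1, prob = c(0.9, 0.1)))
  }, "")
}

# default per-arm clonotype-level phenotype transition kernels
default_transition_kernels <- function() {
  ph <- default_phenotypes()
  mk <- function(treg_row, cd4_to_treg) {
    K <- matrix(0, 8, 8, dimnames = list(ph, ph))
    K["Treg", ] <- treg_row
    K["CD4_naive", c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem")] <-
      c(cd4_to_treg, 0.80, 0.15 - cd4_to_treg, 0.05)
    K["CD4_Tcm", c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem")] <-
      c(cd4_to_treg, 0.02, 0.83 - cd4_to_treg, 0.15)
    K["CD4_Tem", c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem")] <-
      c(cd4_to_treg, 0.01, 0.12, 0.87 - cd4_to_treg)
    K["CD8_naive", c("CD8_naive", "CD8_Tcm", "CD8_Tem", "CD8_Temra")] <-
      c(0.85, 0.10, 0.04, 0.01)
    K["CD8_Tcm", c("CD8_naive", "CD8_Tcm", "CD8_Tem", "CD8_Temra")] <-
      c(0.03, 0.82, 0.12, 0.03)
    K["CD8_Tem", c("CD8_naive", "CD8_Tcm", "CD8_Tem", "CD8_Temra")] <-
      c(0.01, 0.08, 0.81, 0.10)
    K["CD8_Temra", c("CD8_naive", "CD8_Tcm", "CD8_Tem", "CD8_Temra")] <-
      c(0.01, 0.02, 0.07, 0.90)
    stopifnot(all(abs(rowSums(K) - 1) < 1e-12))
    K
  }
  treg_placebo <- setNames(numeric(8), ph)
  treg_placebo[c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem")] <- c(0.35, 0.05, 0.20, 0.40)
  treg_il2 <- setNames(numeric(8), ph)
  treg_il2[c("Treg", "CD4_naive", "CD4_Tcm", "CD4_Tem")] <- c(0.80, 0.05, 0.10, 0.05)
  list(placebo = mk(treg_placebo, 0.02),
       IL2_1.5 = mk(treg_il2, 0.10),
       IL2_2.5 = mk(treg_il2, 0.10))
}

#' Simulation configuration for the synthetic cohort
#'
#' Defaults emulate a three-arm low-dose IL-2 trial design: placebo
#' (4 patients), 1.5 MIU/day (6) and 2.5 MIU/day (6), two timepoints per
#' patient, a geometric clonotype-size law, Treg proportions of 2%
#' pre-treatment rising to 4/6/9% post by arm, arm-dependent clonotype
#' persistence targeting shared-cell fractions of about 1.5/7.1/3.5%,
#' and arm-dependent phenotype transition kernels (placebo polarizes
#' away from Treg; IL-2 arms retain it).
#'
#' @param seed Integer RNG seed (required for reproducible cohorts).
#' @param cells_per_sample Cells per patient-timepoint sample.
#' @param arms Named integer vector of patients per arm.
#' @param treg_pre Pre-treatment Treg cell fraction (all arms).
#' @param treg_post Named per-arm post-treatment Treg fractions.
#' @param clone_size_p_pre Geometric parameter of the pre clone-size law.
#' @param clone_size_p_post Named per-arm post geometric parameters
#'   (smaller = heavier expansion).
#' @param clone_size_max Truncation of the clone-size law.
#' @param persistence Named per-arm clonotype persistence probabilities.
#' @param kernels Per-arm 8 x 8 phenotype transition kernels
#'   (rows sum to 1); default [default_transition_kernels()].
#' @param label_noise Cell-level phenotype label noise: with this
#'   probability a cell's label is redrawn from the sample's phenotype
#'   distribution (keeping marginals exact).
#' @param defect_rates Named rates of planted QC defects
#'   (`multi_chain`, `orphan`, `nonproductive`).
#' @param invariant_rate Clonotype-level rate of invariant (MAIT/iNKT)
#'   receptors.
#' @param motif_families List of planted beta-CDR3 motif families, each
#'   `list(motif =, n =)` (n = number of carrier clonotypes).
#' @param expression List of expression-block parameters: `n_genes`,
#'   `n_de`, `de_log2fc`, `nb_size`, `base_mean_meanlog`,
#'   `base_mean_sdlog`.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    cells_per_sample = 2500,
    arms = c(placebo = 4L, IL2_1.5 = 6L, IL2_2.5 = 6L),
    treg_pre = 0.02,
    treg_post = c(placebo = 0.04, IL2_1.5 = 0.06, IL2_2.5 = 0.09),
    clone_size_p_pre = 0.7,
    clone_size_p_post = c(placebo = 0.7, IL2_1.5 = 0.6, IL2_2.5 = 0.55),
    clone_size_max = 1000,
    persistence = c(placebo = 0.015, IL2_1.5 = 0.071, IL2_2.5 = 0.035),
    kernels = default_transition_kernels(),
    label_noise = 0.10,
    defect_rates = c(multi_chain = 0.006, orphan = 0.33, nonproductive = 0.06),
    invariant_rate = 0.005,
    motif_families = list(fam1 = list(motif = "RQGW", n = 10),
                          fam2 = list(motif = "SYEQ", n = 10)),
    expression = list(n_genes = 2000, n_de = 30, de_log2fc = 1,
                      nb_size = 2, base_mean_meanlog = log(0.3),
                      base_mean_sdlog = 0.8)) {
  stopifnot(all(names(arms) %in% ARM_LEVELS), all(arms >= 1))
  probs <- c(treg_pre, treg_post, persistence, label_noise, defect_rates,
             invariant_rate, clone_size_p_pre, clone_size_p_post)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (sum(defect_rates) + invariant_rate >= 1)
    abort("defect rates leave no clean cells")
  for (a in names(kernels))
    if (any(abs(rowSums(kernels[[a]]) - 1) > 1e-9))
      abort(sprintf("kernel rows for arm %s must sum to 1", a))
  structure(list(
    seed = as.integer(seed), cells_per_sample = cells_per_sample,
    arms = arms, treg_pre = treg_pre, treg_post = treg_post,
    clone_size_p_pre = clone_size_p_pre,
    clone_size_p_post = clone_size_p_post,
    clone_size_max = clone_size_max, persistence = persistence,
    kernels = kernels, label_noise = label_noise,
    defect_rates = defect_rates, invariant_rate = invariant_rate,
    motif_families = motif_families, expression = expression),
    class = "sim_config")
}

# sample-level phenotype distribution: Treg fraction t, other labels share
# the remainder with fixed relative weights
phenotype_weights <- function(treg_frac) {
  base <- c(CD4_naive = 0.25, CD4_Tcm = 0.20, CD4_Tem = 0.15,
            CD8_naive = 0.12, CD8_Tcm = 0.10, CD8_Tem = 0.10,
            CD8_Temra = 0.08)
  w <- c(Treg = treg_frac, base / sum(base) * (1 - treg_frac))
  w[default_phenotypes()]
}

# geometric (truncated) clone sizes filling exactly `total` cells
draw_clone_sizes <- function(total, p, cap) {
  sizes <- integer(0)
  while (sum(sizes) < total) {
    need <- total - sum(sizes)
    batch <- pmin(rgeom(max(32L, ceiling(need * p)), p) + 1L, cap)
    sizes <- c(sizes, batch)
  }
  cum <- cumsum(sizes)
  k <- which(cum >= total)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - total)
  sizes[sizes > 0]
}

# noise kernel that redraws from the sample distribution w: marginals are
# preserved exactly and pre/post cell labels stay independent given the
# clonotype's base phenotype, so the effective cell-level transition
# kernel is available in closed form (see effective_cd4_kernel)
apply_label_noise <- function(base, noise, w) {
  n <- length(base)
  flip <- runif(n) < noise
  base[flip] <- sample(names(w), sum(flip), replace = TRUE, prob = w)
  base
}

# closed-form cell-level CD4 transition kernel implied by the planted
# clonotype kernel K, sample phenotype weights and the label noise
effective_cd4_kernel <- function(K, w_pre, w_post, noise,
                                 collapse_map = cd4_collapse_map()) {
  ph <- rownames(K)
  Npre <- (1 - noise) * diag(length(ph)) +
    noise * matrix(w_pre[ph], length(ph), length(ph), byrow = TRUE)
  Npost <- (1 - noise) * diag(length(ph)) +
    noise * matrix(w_post[ph], length(ph), length(ph), byrow = TRUE)
  dimnames(Npre) <- dimnames(Npost) <- list(ph, ph)
  J <- t(Npre) %*% diag(w_pre[ph]) %*% (K %*% Npost) # J[i,j] over emitted labels
  dimnames(J) <- list(ph, ph)
  sel <- names(collapse_map)
  Jc <- J[sel, sel]
  dimnames(Jc) <- list(unname(collapse_map[sel]), unname(collapse_map[sel]))
  Jc / rowSums(Jc)
}

#' Simulate a longitudinal paired scTCR + phenotype cohort
#'
#' Per patient and timepoint, clonotype frequencies follow a truncated
#' geometric law; each clonotype carries a germline-like alpha/beta CDR3
#' pair, V/J genes and a base phenotype; post-timepoint samples retain
#' each pre clonotype with the arm's persistence probability and evolve
#' its phenotype by the arm's transition kernel; planted beta-CDR3 motif
#' families, invariant TCRs and QC defects (multi-chain, orphan,
#' non-productive cells) are injected at the configured rates. All draws
#' come from the seeded generator, so a fixed config reproduces the
#' cohort exactly.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_study`: `chains` (AIRR-style chain
#'   tibble), `meta` (cell metadata) and `truth` (ground-truth list:
#'   per-cell table, per-clonotype table, planted kernels and their
#'   effective CD4 cell-level versions, motif-family table, config).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  ph <- default_phenotypes()
  clone_rows <- list(); cell_rows <- list()
  uid_counter <- 0L
  for (arm in names(config$arms)) {
    K <- config$kernels[[arm]]
    w_pre <- phenotype_weights(config$treg_pre)
    w_post <- phenotype_weights(config$treg_post[[arm]])
    for (pi in seq_len(config$arms[[arm]])) {
      patient <- sprintf("%s_pt%02d", arm, pi)
      # --- pre timepoint clonotypes
      sz_pre <- draw_clone_sizes(config$cells_per_sample,
                                 config$clone_size_p_pre, config$clone_size_max)
      n_pre <- length(sz_pre)
      base_pre <- sample(ph, n_pre, replace = TRUE, prob = w_pre)
      persist <- runif(n_pre) < config$persistence[[arm]]
      uids <- sprintf("%s_cl%05d", patient, uid_counter + seq_len(n_pre))
      uid_counter <- uid_counter + n_pre
      pre <- tibble(
        clone_uid = uids, patient_id = patient, arm = arm,
        alpha_cdr3 = simulate_naive_cdr3(n_pre),
        beta_cdr3 = simulate_naive_cdr3(n_pre),
        alpha_v = sample(TRAV_POOL, n_pre, TRUE, gene_probs(TRAV_POOL)),
        alpha_j = sample(TRAJ_POOL, n_pre, TRUE, gene_probs(TRAJ_POOL)),
        beta_v = sample(TRBV_POOL, n_pre, TRUE, gene_probs(TRBV_POOL)),
        beta_j = sample(TRBJ_POOL, n_pre, TRUE, gene_probs(TRBJ_POOL)),
        base_pre = base_pre, size_pre = sz_pre, persistent = persist)
      # invariant receptors at clonotype level
      inv <- runif(n_pre) < config$invariant_rate
      if (any(inv)) {
        rules <- default_invariant_rules()
        pick <- sample(nrow(rules), sum(inv), replace = TRUE)
        pre$alpha_v[inv] <- rules$v_gene[pick]
        pre$alpha_j[inv] <- rules$j_gene[pick]
      }
      pre$invariant <- inv
      # --- post timepoint: persisted clones + new clones
      persisted <- pre[pre$persistent, , drop = FALSE]
      if (nrow(persisted)) {
        persisted$size_post <- pmin(
          rgeom(nrow(persisted), config$clone_size_p_post[[arm]]) + 1L,
          config$clone_size_max)
        over <- sum(persisted$size_post) - config$cells_per_sample
        if (over > 0) { # pathological configs only
          persisted <- persisted[cumsum(persisted$size_post) <=
                                   config$cells_per_sample, , drop = FALSE]
        }
        persisted$base_post <- vapply(persisted$base_pre, function(b)
          sample(ph, 1, prob = K[b, ]), "")
      } else {
        persisted$size_post <- integer(0)
        persisted$base_post <- character(0)
      }
      n_fill <- config$cells_per_sample - sum(persisted$size_post)
      sz_new <- draw_clone_sizes(n_fill, config$clone_size_p_post[[arm]],
                                 config$clone_size_max)
      n_new <- length(sz_new)
      uids_new <- sprintf("%s_cl%05d", patient, uid_counter + seq_len(n_new))
      uid_counter <- uid_counter + n_new
      inv_new <- runif(n_new) < config$invariant_rate
      new_post <- tibble(
        clone_uid = uids_new, patient_id = patient, arm = arm,
        alpha_cdr3 = simulate_naive_cdr3(n_new),
        beta_cdr3 = simulate_naive_cdr3(n_new),
        alpha_v = sample(TRAV_POOL, n_new, TRUE, gene_probs(TRAV_POOL)),
        alpha_j = sample(TRAJ_POOL, n_new, TRUE, gene_probs(TRAJ_POOL)),
        beta_v = sample(TRBV_POOL, n_new, TRUE, gene_probs(TRBV_POOL)),
        beta_j = sample(TRBJ_POOL, n_new, TRUE, gene_probs(TRBJ_POOL)),
        base_pre = NA_character_, size_pre = 0L, persistent = FALSE,
        invariant = inv_new,
        size_post = sz_new,
        base_post = sample(ph, n_new, replace = TRUE, prob = w_post))
      if (any(inv_new)) {
        rules <- default_invariant_rules()
        pick <- sample(nrow(rules), sum(inv_new), replace = TRUE)
        new_post$alpha_v[inv_new] <- rules$v_gene[pick]
        new_post$alpha_j[inv_new] <- rules$j_gene[pick]
      }
      pre$size_post <- ifelse(pre$clone_uid %in% persisted$clone_uid,
                              persisted$size_post[match(pre$clone_uid,
                                                        persisted$clone_uid)], 0L)
      pre$base_post <- persisted$base_post[match(pre$clone_uid, persisted$clone_uid)]
      clones <- dplyr::bind_rows(pre, new_post)
      clone_rows[[length(clone_rows) + 1L]] <- clones
      # --- cells
      for (tp in c("pre", "post")) {
        sz <- if (tp == "pre") clones$size_pre else clones$size_post
        base <- if (tp == "pre") clones$base_pre else clones$base_post
        w <- if (tp == "pre") w_pre else w_post
        keep <- sz > 0
        if (!any(keep)) next
        idx <- rep(which(keep), sz[keep])
        n_cells <- length(idx)
        phen <- apply_label_noise(base[idx], config$label_noise, w)
        cell_rows[[length(cell_rows) + 1L]] <- tibble(
          cell_id = sprintf("%s_%s_c%05d", patient, tp, seq_len(n_cells)),
          patient_id = patient, timepoint = tp, arm = arm,
          clone_uid = clones$clone_uid[idx],
          base_phenotype = base[idx], phenotype = phen)
      }
    }
  }
  clones <- dplyr::bind_rows(clone_rows)
  cells <- dplyr::bind_rows(cell_rows)
  

  # --- planted beta motif families (distinct clonotypes share a k-mer)
  fam_rows <- list()
  if (length(config$motif_families)) {
    taken <- character(0)
    for (fam in names(config$motif_families)) {
      f <- config$motif_families[[fam]]
      # prefer post-timepoint Treg-based clonotypes, fall back to any
      cand <- clones$clone_uid[clones$size_post > 0 &
                                 !clones$clone_uid %in% taken &
                                 !is.na(clones$base_post) &
                                 clones$base_post == "Treg"]
      if (length(cand) < f$n)
        cand <- c(cand, setdiff(clones$clone_uid[clones$size_post > 0],
                                c(taken, cand)))
      sel <- head(cand, f$n)
      taken <- c(taken, sel)
      ii <- match(sel, clones$clone_uid)
      clones$beta_cdr3[ii] <- vapply(seq_along(ii), function(z)
        plant_motif(f$motif), "")
      fam_rows[[fam]] <- tibble(family = fam, motif = f$motif, clone_uid = sel)
    }
  }
  motif_truth <- if (length(fam_rows)) dplyr::bind_rows(fam_rows) else
    tibble(family = character(), motif = character(), clone_uid = character())

  # --- QC defects at cell level
  dr <- config$defect_rates
  u <- runif(nrow(cells))
  defect <- rep("clean", nrow(cells))
  defect[u < dr[["multi_chain"]]] <- "multi_chain"
  defect[u >= dr[["multi_chain"]] &
           u < dr[["multi_chain"]] + dr[["orphan"]]] <- "orphan"
  defect[u >= dr[["multi_chain"]] + dr[["orphan"]] &
           u < sum(dr)] <- "nonproductive"
  cells$defect <- defect
  cells$invariant <- clones$invariant[match(cells$clone_uid, clones$clone_uid)]

  # --- emit chains
  ci <- match(cells$clone_uid, clones$clone_uid)
  mk_chain <- function(locus, cdr3, v, j, productive) tibble(
    cell_id = cells$cell_id, locus = locus, cdr3_aa = cdr3,
    cdr3_nt = NA_character_, v_gene = v, j_gene = j,
    productive = productive, umis = rgeom(nrow(cells), 0.4) + 1L)
  alpha <- mk_chain("TRA", clones$alpha_cdr3[ci], clones$alpha_v[ci],
                    clones$alpha_j[ci], cells$defect != "nonproductive")
  beta <- mk_chain("TRB", clones$beta_cdr3[ci], clones$beta_v[ci],
                   clones$beta_j[ci], cells$defect != "nonproductive")
  # orphan: drop one locus; multi-chain: add a second productive beta
  is_orphan <- cells$defect == "orphan"
  drop_alpha <- is_orphan & runif(nrow(cells)) < 0.5
  alpha <- alpha[!drop_alpha[match(alpha$cell_id, cells$cell_id)], , drop = FALSE]
  beta <- beta[!(is_orphan & !drop_alpha)[match(beta$cell_id, cells$cell_id)], ,
               drop = FALSE]
  multi_ids <- cells$cell_id[cells$defect == "multi_chain"]
  extra <- NULL
  if (length(multi_ids)) {
    extra <- tibble(
      cell_id = multi_ids, locus = "TRB",
      cdr3_aa = simulate_naive_cdr3(length(multi_ids)),
      cdr3_nt = NA_character_,
      v_gene = sample(TRBV_POOL, length(multi_ids), TRUE),
      j_gene = sample(TRBJ_POOL, length(multi_ids), TRUE),
      productive = TRUE, umis = rgeom(length(multi_ids), 0.4) + 1L)
  }
  chains <- dplyr::bind_rows(alpha, beta, extra)
  chains <- dplyr::arrange(chains, .data$cell_id, .data$locus, .data$cdr3_aa)

  meta <- cells[, c("cell_id", "patient_id", "timepoint", "arm", "phenotype")]

  # --- truth: expanded-Treg labels (post timepoint, emitted labels)
  post_treg <- cells$timepoint == "post" & cells$phenotype == "Treg" &
    cells$defect == "clean" & !cells$invariant
  key <- paste(cells$patient_id, cells$clone_uid)
  treg_counts <- table(key[post_treg])
  cells$expanded_treg <- post_treg &
    as.integer(treg_counts[key]) >= 2L & !is.na(treg_counts[key])

  kernel_effective <- lapply(names(config$arms), function(a)
    effective_cd4_kernel(config$kernels[[a]],
                         phenotype_weights(config$treg_pre),
                         phenotype_weights(config$treg_post[[a]]),
                         config$label_noise))
  names(kernel_effective) <- names(config$arms)

  truth <- list(cells = cells, clones = clones,
                kernels = config$kernels,
                kernel_effective = kernel_effective,
                persistence = config$persistence,
                treg_pre = config$treg_pre, treg_post = config$treg_post,
                motif_families = motif_truth, config = config)
  structure(list(chains = chains, meta = meta, truth = truth),
            class = "sim_study")
}

# random CDR3 carrying `motif` in its trimmed interior at a jittered
# start position (0-based shift 0..3)
plant_motif <- function(motif, min_len = 14, max_len = 18) {
  k <- nchar(motif)
  L <- sample(min_len:max_len, 1)
  s <- sample(0:3, 1) # trimmed-coordinate start
  base <- simulate_naive_cdr3(1, min_len = L, max_len = L)
  start <- 4L + s # full-sequence position after the 3-residue flank
  stopifnot(start + k - 1 <= L - 3)
  paste0(substr(base, 1, start - 1), motif, substr(base, start + k, L))
}

#' Simulate a log-normalized expression matrix with planted DE genes
#'
#' Negative-binomial counts on a log-normal baseline, log1p-transformed.
#' Planted DE genes have their mean multiplied by `2^de_log2fc` in cells
#' flagged `expanded_treg` in the ground truth, so the expm1-mean log2
#' fold change of the DE stage recovers the planted effect.
#'
#' @param study A `sim_study` from [simulate_study()] (or a truth list).
#' @param cells Optional character vector of cell ids to include
#'   (default: all post-timepoint Treg cells that pass QC in truth).
#' @param seed RNG seed (default: config seed + 1).
#' @return List: `expr` (cells x genes log1p matrix), `de_genes`
#'   (tibble gene, log2fc), `labels` (true expanded flags, named).
#' @export
simulate_expression <- function(study, cells = NULL, seed = NULL) {
  truth <- if (inherits(study, "sim_study")) study$truth else study
  cfg <- truth$config$expression
  tc <- truth$cells
  if (is.null(cells)) {
    sel <- tc$timepoint == "post" & tc$phenotype == "Treg" &
      tc$defect == "clean" & !tc$invariant
    cells <- tc$cell_id[sel]
  }
  tc <- tc[match(cells, tc$cell_id), , drop = FALSE]
  if (anyNA(tc$cell_id)) abort("unknown cell id(s) requested")
  seed <- seed %||% (truth$config$seed + 1L)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    base_mu <- exp(rnorm(cfg$n_genes, cfg$base_mean_meanlog, cfg$base_mean_sdlog))
    de_idx <- sample(cfg$n_genes, cfg$n_de)
    lfc <- rep(cfg$de_log2fc, cfg$n_de)
    expanded <- tc$expanded_treg
    n <- length(cells)
    mu <- matrix(base_mu, n, cfg$n_genes, byrow = TRUE)
    mu[expanded, de_idx] <- sweep(mu[expanded, de_idx, drop = FALSE], 2,
                                  2^lfc, `*`)
    counts <- matrix(rnbinom(n * cfg$n_genes, size = cfg$nb_size, mu = mu),
                     n, cfg$n_genes)
    expr <- log1p(counts)
    dimnames(expr) <- list(cells, genes)
    list(expr = expr,
         de_genes = tibble(gene = genes[de_idx], log2fc = lfc),
         labels = setNames(expanded, cells))
  })
}

#' Emit planted query and reference CDR3 sets for motif clustering
#'
#' Builds an expanded-Treg-like query set, a disease reference sharing
#' the query's planted motif families (`athero_ref`) and a healthy
#' control reference with disjoint motifs (`HC_ref`), so the
#' cross-dataset clustering fraction of the query recovers
#' `query_in_reference` by construction.
#'
#' @param n_query Number of query CDR3s (default 30).
#' @param query_in_reference Fraction of query CDR3s planted into
#'   reference motif families (default 0.9); the remainder shares one
#'   private query-only motif.
#' @param family_size Reference CDR3s per motif family (default 12).
#' @param ref_motifs,hc_motifs,private_motif 4-mer motifs for the
#'   disease reference, healthy-control reference and private query
#'   family.
#' @param seed RNG seed.
#' @param out_dir Optional directory: writes `query.tsv` and
#'   `reference.tsv` (two-column cdr3_aa / dataset_label TSVs).
#' @return List of tibbles `query`, `reference` plus `truth`
#'   (per-CDR3 family membership).
#' @export
emit_reference_cdr3_sets <- function(n_query = 30, query_in_reference = 0.9,
                                     family_size = 12,
                                     ref_motifs = c("RQGW", "SYEQ", "PDRG"),
                                     hc_motifs = c("WNTE", "MKYD"),
                                     private_motif = "HQFV",
                                     seed = 1L, out_dir = NULL) {
  with_seed(seed, {
    n_ref_seeded <- round(n_query * query_in_reference)
    fam_of_query <- c(sample(rep_len(ref_motifs, n_ref_seeded)),
                      rep(private_motif, n_query - n_ref_seeded))
    query <- tibble(
      cdr3_aa = vapply(fam_of_query, plant_motif, ""),
      dataset_label = "expanded_Treg")
    reference <- dplyr::bind_rows(
      tibble(cdr3_aa = vapply(rep(ref_motifs, each = family_size),
                              plant_motif, ""),
             dataset_label = "athero_ref"),
      tibble(cdr3_aa = vapply(rep(hc_motifs, each = family_size),
                              plant_motif, ""),
             dataset_label = "HC_ref"))
    truth <- tibble(cdr3_aa = query$cdr3_aa, family = fam_of_query,
                    in_reference = fam_of_query %in% ref_motifs)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_tsv(query, file.path(out_dir, "query.tsv"), progress = FALSE)
      readr::write_tsv(reference, file.path(out_dir, "reference.tsv"),
                       progress = FALSE)
    }
    list(query = query, reference = reference, truth = truth)
  })
}

#' Write simulation ground truth as JSON
#' @param truth The `truth` element of a `sim_study`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth[setdiff(names(truth), "config")]
  out$kernels <- lapply(out$kernels, function(m) as.data.frame(m))
  out$kernel_effective <- lapply(out$kernel_effective, as.data.frame)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
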
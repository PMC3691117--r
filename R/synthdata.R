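#' Simulation parameters for synthetic expression cohorts
#'
#' Bundles the generative settings for a two-class log2 expression cohort:
#' gene-wise variances are drawn from a scaled inverse-gamma prior
#' (\eqn{1/\sigma^2 \sim \mathrm{Gamma}(a, \mathrm{scale}=b)}), a configurable
#' number of truly differential transcripts receive an additive log2 effect
#' \code{delta} in the case class, and optional A/B technical replicates add
#' Normal noise with sd \code{tau}.
#'
#' @param n_genes number of transcripts.
#' @param n_case,n_control samples per class.
#' @param n_diff number of truly differential transcripts (\code{<= n_genes}).
#' @param delta additive log2 case-vs-control effect; scalar or length
#'   \code{n_diff}.
#' @param delta_standardized if \code{TRUE}, \code{delta} is interpreted in
#'   units of each planted gene's own sd (\eqn{\delta_g = \delta \sigma_g}),
#'   so the planted standardized effect size is exactly \code{delta}.
#' @param a,b shape and scale of the Gamma prior on precisions; both > 0.
#' @param tau technical-replicate noise sd, log2 units, >= 0.
#' @param corrupt_fraction proportion of replicated subjects whose B sample is
#'   corrupted (rank-scrambled), in [0, 1].
#' @param scramble_fraction fraction of genes scrambled within a corrupted B
#'   sample.
#' @param control_gene_id identifier of the designated control gene; defaults
#'   to the first gene.
#' @param seed integer; fully determines all generated output.
#' @return An object of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 1000, n_case = 10, n_control = 10,
                       n_diff = 50, delta = 1, delta_standardized = FALSE,
                       a = 3, b = 1, tau = 0.05,
                       corrupt_fraction = 0, scramble_fraction = 0.3,
                       control_gene_id = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1)
  if (n_diff < 0 || n_diff > n_genes) {
    stop("n_diff must lie in [0, n_genes]", call. = FALSE)
  }
  if (a <= 0 || b <= 0) stop("prior parameters a, b must be > 0", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (corrupt_fraction < 0 || corrupt_fraction > 1) {
    stop("corrupt_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!(length(delta) %in% c(1L, max(n_diff, 1L)))) {
    stop("delta must be scalar or length n_diff", call. = FALSE)
  }
  p <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
            n_control = as.integer(n_control), n_diff = as.integer(n_diff),
            delta = delta, delta_standardized = isTRUE(delta_standardized),
            a = a, b = b, tau = tau,
            corrupt_fraction = corrupt_fraction,
            scramble_fraction = scramble_fraction,
            control_gene_id = control_gene_id, seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

gene_id_vec <- function(n) sprintf("g%05d", seq_len(n))

# Draw the gene-level truth shared by all cohorts of one study:
# baseline means, prior-drawn variances, and the planted differential set.
make_gene_truth <- function(params) {
  with_seed(child_seed(params$seed, 1L), {
    g <- params$n_genes
    gene_ids <- gene_id_vec(g)
    mu0 <- stats::runif(g, 4, 12)
    sigma2 <- 1 / stats::rgamma(g, shape = params$a, scale = params$b)
    planted <- if (params$n_diff > 0) sort(sample.int(g, params$n_diff)) else integer(0)
    delta_g <- numeric(g)
    dd <- rep(params$delta, length.out = params$n_diff)
    if (params$delta_standardized) dd <- dd * sqrt(sigma2[planted])
    delta_g[planted] <- dd
    control_gene <- params$control_gene_id
    if (is.null(control_gene)) control_gene <- gene_ids[1L]
    list(gene_ids = gene_ids, mu0 = mu0, sigma2 = sigma2,
         planted = gene_ids[planted], delta_g = delta_g,
         control_gene_id = control_gene)
  })
}

# Sample one cohort's expression matrix and annotation from a gene truth.
sample_cohort <- function(truth, n_case, n_control, cohort, seed,
                          subject_prefix = cohort) {
  g <- length(truth$gene_ids)
  n <- n_case + n_control
  classes <- c(rep("case", n_case), rep("control", n_control))
  subject_ids <- sprintf("%s_%s_%02d", subject_prefix, classes,
                         c(seq_len(n_case), seq_len(n_control)))
  sample_ids <- subject_ids
  mat <- with_seed(seed, {
    means_case <- truth$mu0 + truth$delta_g
    m <- matrix(NA_real_, g, n)
    sd_g <- sqrt(truth$sigma2)
    for (j in seq_len(n)) {
      mu <- if (classes[j] == "case") means_case else truth$mu0
      m[, j] <- stats::rnorm(g, mu, sd_g)
    }
    m
  })
  dimnames(mat) <- list(truth$gene_ids, sample_ids)
  annot <- data.frame(sample_id = sample_ids, class = classes,
                      cohort = cohort, subject_id = subject_ids,
                      replicate_role = "none", stringsAsFactors = FALSE)
  list(matrix = mat, annot = annot)
}

#' Generate a synthetic two-class expression cohort
#'
#' Per gene, a variance is drawn from the scaled inverse-gamma prior, a
#' baseline log2 mean from Uniform(4, 12), and samples from
#' \eqn{N(\mu_g, \sigma_g^2)}; the \code{n_diff} planted transcripts get case
#' mean \eqn{\mu_g + \delta_g}. Deterministic given \code{params$seed}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param cohort cohort label for the annotation.
#' @return list with \code{matrix} (genes x samples, log2), \code{annot}
#'   (sample annotation data frame) and \code{truth} (planted gene ids,
#'   true means/variances, seed).
#' @export
generate_cohort <- function(params, cohort = "training") {
  stopifnot(inherits(params, "sim_params"))
  truth <- make_gene_truth(params)
  co <- sample_cohort(truth, params$n_case, params$n_control, cohort,
                      child_seed(params$seed, 2L))
  list(matrix = co$matrix, annot = co$annot,
       truth = list(planted_gene_ids = truth$planted,
                    mu0 = stats::setNames(truth$mu0, truth$gene_ids),
                    delta_g = stats::setNames(truth$delta_g, truth$gene_ids),
                    sigma2 = stats::setNames(truth$sigma2, truth$gene_ids),
                    control_gene_id = truth$control_gene_id,
                    corrupted_replicate_ids = character(0),
                    seed = params$seed))
}

#' Append B technical replicates to a cohort
#'
#' For each requested subject, appends a B sample equal to the subject's A
#' sample plus per-gene Normal(0, tau^2) technical noise. Subjects listed in
#' \code{corrupt_subjects} additionally have a fraction of their B-sample
#' genes rank-scrambled (values permuted among those genes), which destroys
#' rank concordance without changing the marginal distribution.
#'
#' @param matrix genes x samples log2 matrix.
#' @param annot sample annotation (see \code{\link{generate_cohort}}).
#' @param tau technical noise sd (log2), >= 0.
#' @param subjects subjects to replicate; default all subjects in
#'   \code{annot} with role \code{"none"}.
#' @param corrupt_subjects subset of \code{subjects} whose B sample is
#'   corrupted.
#' @param scramble_fraction fraction of genes scrambled in corrupted B
#'   samples (default 0.3).
#' @param seed integer seed.
#' @param replicate_cohort cohort label given to the new B samples; default
#'   keeps the subject's own cohort.
#' @return list with the augmented \code{matrix} and \code{annot}.
#' @export
add_replicates <- function(matrix, annot, tau = 0.05, subjects = NULL,
                           corrupt_subjects = character(0),
                           scramble_fraction = 0.3, seed = 1L,
                           replicate_cohort = NULL) {
  stopifnot(tau >= 0)
  if (is.null(subjects)) {
    subjects <- annot$subject_id[annot$replicate_role == "none"]
  }
  if (!all(subjects %in% annot$subject_id)) {
    stop("subjects not present in annotation: ",
         paste(setdiff(subjects, annot$subject_id), collapse = ", "),
         call. = FALSE)
  }
  if (!all(corrupt_subjects %in% subjects)) {
    stop("corrupt_subjects must be a subset of subjects", call. = FALSE)
  }
  if (length(subjects) == 0L) {
    return(list(matrix = matrix, annot = annot))
  }
  if (any(annot$replicate_role[annot$subject_id %in% subjects] == "B")) {
    stop("subject already has a B replicate", call. = FALSE)
  }
  g <- nrow(matrix)
  new_cols <- NULL
  new_rows <- list()
  with_seed(seed, {
    for (s in subjects) {
      i <- which(annot$subject_id == s & annot$replicate_role %in% c("none", "A"))
      if (length(i) != 1L) stop("subject ", s, " ambiguous in annotation", call. = FALSE)
      b <- matrix[, annot$sample_id[i]] + stats::rnorm(g, 0, tau)
      if (s %in% corrupt_subjects && scramble_fraction > 0) {
        k <- max(2L, round(scramble_fraction * g))
        idx <- sample.int(g, k)
        b[idx] <- b[sample(idx)]
      }
      new_cols <- cbind(new_cols, b)
      new_rows[[s]] <- data.frame(
        sample_id = paste0(s, "_B"), class = annot$class[i],
        cohort = if (is.null(replicate_cohort)) annot$cohort[i] else replicate_cohort,
        subject_id = s, replicate_role = "B", stringsAsFactors = FALSE)
      annot$replicate_role[i] <- "A"
    }
  })
  colnames(new_cols) <- vapply(new_rows, function(r) r$sample_id, "")
  rownames(new_cols) <- rownames(matrix)
  list(matrix = cbind(matrix, new_cols),
       annot = rbind(annot, do.call(rbind, unname(new_rows))))
}

#' Generate linear-scale probe-level data for summarization tests
#'
#' Expands a gene-level truth matrix into probe intensities
#' \eqn{2^{(\mathrm{gene} + \mathrm{affinity} + \mathrm{noise})}} with a fixed
#' per-probe affinity shared across samples, mimicking multi-probe probe sets.
#'
#' @param params a \code{\link{sim_params}} object (gene-level truth).
#' @param probes_per_set probes per probe set, >= 1.
#' @param affinity_sd sd of fixed per-probe affinities (log2), default 0.5.
#' @param noise_sd sd of probe-level measurement noise (log2), default 0.1.
#' @return list with \code{probes} (linear intensities, probes x samples),
#'   \code{probe_ids}, \code{probeset_ids} (parallel to rows), and
#'   \code{gene_matrix} (the true log2 gene matrix).
#' @export
generate_probe_level <- function(params, probes_per_set = 11,
                                 affinity_sd = 0.5, noise_sd = 0.1) {
  stopifnot(probes_per_set >= 1)
  co <- generate_cohort(params)
  gm <- co$matrix
  g <- nrow(gm); n <- ncol(gm); p <- probes_per_set
  out <- with_seed(child_seed(params$seed, 3L), {
    affin <- stats::rnorm(g * p, 0, affinity_sd)
    log2probe <- gm[rep(seq_len(g), each = p), , drop = FALSE] + affin +
      matrix(stats::rnorm(g * p * n, 0, noise_sd), g * p, n)
    2^log2probe
  })
  probeset_ids <- rep(rownames(gm), each = p)
  probe_ids <- paste0(probeset_ids, "_p", rep(seq_len(p), times = g))
  rownames(out) <- probe_ids
  colnames(out) <- colnames(gm)
  list(probes = out, probe_ids = probe_ids, probeset_ids = probeset_ids,
       gene_matrix = gm)
}

#' Generate a complete multi-cohort synthetic study
#'
#' Draws one shared gene-level truth and samples enrichment, training and test
#' cohorts from it, then adds B technical replicates for a designated set of
#' subjects (the replicate cohort). Mirrors a two-stage biomarker design: a
#' small enrichment group used only for univariate filtering, a larger
#' training group for model building, technical replicates for reproducibility
#' assessment, and a small independent test set.
#'
#' @param params a \code{\link{sim_params}} object; its \code{n_case},
#'   \code{n_control} are ignored in favour of the cohort sizes below.
#' @param enrichment,training,test integer vectors \code{c(case, control)}.
#' @param n_replicates number of subjects (drawn from enrichment + training)
#'   given B replicates.
#' @param corrupt_subjects subjects whose B replicate is corrupted; default
#'   chosen by \code{params$corrupt_fraction}.
#' @return list with \code{matrix}, \code{annot}, \code{truth}.
#' @export
generate_study <- function(params, enrichment = c(3, 13),
                           training = c(26, 12), test = c(3, 3),
                           n_replicates = 34, corrupt_subjects = NULL) {
  stopifnot(inherits(params, "sim_params"))
  truth <- make_gene_truth(params)
  enr <- sample_cohort(truth, enrichment[1], enrichment[2], "enrichment",
                       child_seed(params$seed, 11L))
  trn <- sample_cohort(truth, training[1], training[2], "training",
                       child_seed(params$seed, 12L))
  tst <- sample_cohort(truth, test[1], test[2], "test",
                       child_seed(params$seed, 13L))
  mat <- cbind(enr$matrix, trn$matrix, tst$matrix)
  annot <- rbind(enr$annot, trn$annot, tst$annot)
  pool <- annot$subject_id[annot$cohort %in% c("enrichment", "training")]
  n_replicates <- min(n_replicates, length(pool))
  rep_subjects <- with_seed(child_seed(params$seed, 14L),
                            sample(pool, n_replicates))
  if (is.null(corrupt_subjects)) {
    n_corrupt <- round(params$corrupt_fraction * n_replicates)
    corrupt_subjects <- with_seed(child_seed(params$seed, 15L),
                                  if (n_corrupt > 0) sample(rep_subjects, n_corrupt)
                                  else character(0))
  }
  out <- add_replicates(mat, annot, tau = params$tau, subjects = rep_subjects,
                        corrupt_subjects = corrupt_subjects,
                        scramble_fraction = params$scramble_fraction,
                        seed = child_seed(params$seed, 16L),
                        replicate_cohort = "replicate")
  list(matrix = out$matrix, annot = out$annot,
       truth = list(planted_gene_ids = truth$planted,
                    mu0 = stats::setNames(truth$mu0, truth$gene_ids),
                    delta_g = stats::setNames(truth$delta_g, truth$gene_ids),
                    sigma2 = stats::setNames(truth$sigma2, truth$gene_ids),
                    control_gene_id = truth$control_gene_id,
                    replicated_subjects = rep_subjects,
                    corrupted_replicate_ids = corrupt_subjects,
                    seed = params$seed))
}
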
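#' Read / write a log2 expression matrix as TSV
#'
#' Format: header row of sample ids, first column gene ids, values written
#' with 6 decimal places (round-trip identity to 6 decimals; row and column
#' order preserved).
#'
#' @param path file path.
#' @return \code{read_expression_tsv} returns a numeric matrix with gene ids
#'   as row names and sample ids as column names.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression TSV needs a header and data", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stop("ragged row at line ", which(nf != length(header))[1] + 1L, call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    stop("duplicate gene id '", dup, "' at line ",
         which(gene_ids == dup)[2] + 1L, call. = FALSE)
  }
  m <- do.call(rbind, lapply(body, function(r) {
    suppressWarnings(as.numeric(r[-1]))
  }))
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("non-numeric cell at line ", bad + 1L, call. = FALSE)
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' @rdname read_expression_tsv
#' @param matrix genes x samples numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.6f", matrix[i, ])),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample annotation table as TSV
#'
#' Columns: sample_id, class, cohort, subject_id, replicate_role.
#' @param path file path.
#' @export
read_annotation_tsv <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "cohort", "subject_id", "replicate_role")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(a$sample_id)) stop("duplicate sample ids in annotation",
                                       call. = FALSE)
  a[need]
}

#' @rdname read_annotation_tsv
#' @param annot annotation data frame.
#' @export
write_annotation_tsv <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 expression file
#'
#' Convenience reader for the broad GCT 1.2 format (versioned header, row
#' count line, Name/Description columns); only the Name column is kept as the
#' gene id.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || trimws(lines[1]) != "#1.2") {
    stop("not a GCT 1.2 file", call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-(1:2)]
  body <- strsplit(lines[3 + seq_len(dims[1])], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(r) as.numeric(r[-(1:2)]),
                   numeric(length(sample_ids))))
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Pipeline configuration
#'
#' Bundles every tunable of the discovery workflow. Defaults follow the
#' canonical published settings of this design: enrichment threshold
#' \code{alpha = 0.05} (unadjusted), panel size \code{target_n = 10}, DLDA
#' classifier, \code{B = 1000} permutations, replicate QC at
#' \code{rho_min = 0.985} and \code{z_max = 2.3}.
#'
#' @param alpha univariate enrichment threshold.
#' @param target_n panel size.
#' @param classifier classifier type (see \code{\link{panel_train}}).
#' @param cost SVM soft-margin cost.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param rho_min,z_max,fail_count_to_drop replicate QC thresholds.
#' @param control_gene_id control gene for the QC check.
#' @param strict_rfe one-gene-at-a-time elimination.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(alpha = 0.05, target_n = 10, classifier = "dlda",
                            cost = 1, B = 1000, seed = 1L, rho_min = 0.985,
                            z_max = 2.3, fail_count_to_drop = 2,
                            control_gene_id = NULL, strict_rfe = FALSE) {
  cfg <- list(alpha = alpha, target_n = as.integer(target_n),
              classifier = match.arg(classifier, CLASSIFIERS),
              cost = cost, B = as.integer(B), seed = as.integer(seed),
              qc = qc_thresholds(rho_min, z_max, fail_count_to_drop),
              control_gene_id = control_gene_id, strict_rfe = strict_rfe)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full biomarker discovery workflow
#'
#' Executes the staged design on an annotated expression matrix: replicate QC
#' (2-of-3 drop rule) -> univariate random-variance enrichment on the
#' enrichment cohort -> SVM-RFE panel selection and classifier training on
#' the training cohort -> nested LOOCV with permutation significance ->
#' frozen-model evaluation of the enrichment, replicate and test cohorts ->
#' per-cohort report. All artifacts are written to \code{out_dir} together
#' with a manifest (config, config hash, seed, completed stages).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param matrix genes x samples log2 matrix (or \code{matrix_path}).
#' @param annot annotation data frame (or \code{annot_path}).
#' @param out_dir output directory (created if needed).
#' @param matrix_path,annot_path TSV inputs, read when the in-memory objects
#'   are not given.
#' @return (invisibly) a list with the report data frame and all stage
#'   results.
#' @export
run_pipeline <- function(config, matrix = NULL, annot = NULL,
                         out_dir = tempfile("panelcv_run_"),
                         matrix_path = NULL, annot_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(config)
  cfg_plain$qc <- unclass(cfg_plain$qc)
  manifest <- list(config = cfg_plain,
                   config_hash = config_hash(jsonlite::toJSON(cfg_plain,
                                                              auto_unbox = TRUE)),
                   seed = config$seed, stages = character(0))
  finish_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  on.exit(finish_manifest())

  if (is.null(matrix)) matrix <- read_expression_tsv(matrix_path)
  if (is.null(annot)) annot <- read_annotation_tsv(annot_path)

  # --- replicate QC ---------------------------------------------------------
  log_stage("qc", "replicate concordance checks")
  has_pairs <- any(annot$replicate_role == "B")
  if (has_pairs) {
    ctrl <- config$control_gene_id
    if (is.null(ctrl)) ctrl <- rownames(matrix)[1]
    qc <- assess_replicates(matrix, annot, ctrl, config$qc)
    annot_f <- attr(qc, "filtered_annot")
    utils::write.table(as.data.frame(qc), file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    qc <- NULL
    annot_f <- annot
  }
  write_annotation_tsv(annot_f, file.path(out_dir, "filtered_annotation.tsv"))
  manifest$stages <- c(manifest$stages, "qc")

  # --- enrichment filter ----------------------------------------------------
  log_stage("select", "random-variance t-test on enrichment cohort")
  enr <- annot_f[annot_f$cohort == "enrichment" &
                   annot_f$replicate_role != "B", , drop = FALSE]
  if (nrow(enr) < 4) stop("enrichment cohort too small", call. = FALSE)
  st <- rvm_t_test(matrix[, enr$sample_id, drop = FALSE], enr$class)
  enriched <- select_features(st, config$alpha)
  if (length(enriched) < config$target_n) {
    manifest$error <- "enrichment filter retained fewer genes than target_n"
    stop("enrichment filter retained ", length(enriched),
         " genes (< target_n = ", config$target_n, ")", call. = FALSE)
  }
  writeLines(enriched, file.path(out_dir, "enriched_genes.txt"))
  manifest$stages <- c(manifest$stages, "select")

  # --- training: RFE + classifier ------------------------------------------
  log_stage("train", "SVM-RFE to ", config$target_n, " genes + ",
            config$classifier, " on training cohort")
  trn <- annot_f[annot_f$cohort == "training" &
                   annot_f$replicate_role != "B", , drop = FALSE]
  xt <- matrix[, trn$sample_id, drop = FALSE]
  panel <- svm_rfe(xt, trn$class, enriched, target_n = config$target_n,
                   cost = config$cost, strict = config$strict_rfe)
  model <- panel_train(xt, trn$class, panel, method = config$classifier,
                       cost = config$cost)
  write_gene_model(model, file.path(out_dir, "gene_model.json"))
  manifest$stages <- c(manifest$stages, "train")

  # --- nested LOOCV + permutation ------------------------------------------
  log_stage("crossval", "nested LOOCV with B = ", config$B, " permutations")
  perm <- permutation_test(xt, trn$class, enriched,
                           target_n = config$target_n,
                           method = config$classifier, cost = config$cost,
                           B = config$B, seed = child_seed(config$seed, 21L))
  cv <- perm$observed
  utils::write.table(cv$predictions,
                     file.path(out_dir, "cv_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(error_rate = cv$error_rate, p = perm$p,
                            B = perm$B, e_perm = perm$e_perm),
                       file.path(out_dir, "cv_result.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages <- c(manifest$stages, "crossval")

  # --- frozen-model evaluation ---------------------------------------------
  log_stage("predict", "frozen-model evaluation of all cohorts")
  cohorts <- c("training", "enrichment", "replicate", "test")
  rows <- list(); evals <- list()
  for (co in cohorts) {
    ev <- predict_cohort(model, matrix, annot_f, co)
    evals[[co]] <- ev
    if (is.null(ev$summary)) next
    truth <- annot_f$class[match(ev$predictions$sample_id, annot_f$sample_id)]
    fp <- frozen_model_permutation(ev$predictions$class, truth,
                                   B = config$B,
                                   seed = child_seed(config$seed, 22L))
    s <- ev$summary
    rows[[co]] <- data.frame(
      cohort = co, n = s$n_case + s$n_control,
      case_correct = sprintf("%d/%d", s$case_correct, s$n_case),
      control_correct = sprintf("%d/%d", s$control_correct, s$n_control),
      overall_pct = s$overall_pct, sensitivity_pct = s$sensitivity_pct,
      specificity_pct = s$specificity_pct, permutation_p = fp$p,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages <- c(manifest$stages, "predict", "report")
  log_stage("report", "done; artifacts in ", out_dir)

  invisible(list(out_dir = out_dir, qc = qc, enriched = enriched,
                 panel = panel, model = model, cv = cv, perm = perm,
                 evaluations = evals, report = report))
}
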
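#' Eigengenes of a simulated dataset
#'
#' Computes one eigengene per predictor and response module of a
#' `SimDataset` (the simulation study feeds module eigengenes directly to
#' the regression stage; module detection is bypassed because the modules
#' are known by construction).
#'
#' @param ds A `SimDataset` from [simulate_dataset()].
#' @return List with `X_pred` (sample-by-predictor-module eigengene matrix),
#'   `Y_resp`, and `var_explained` for both layers.
#' @export
dataset_eigengenes <- function(ds) {
  stopifnot(inherits(ds, "SimDataset"))
  eg <- function(mats) {
    out <- lapply(mats, function(m) compute_eigengene(standardize_rows(t(m))))
    list(values = do.call(cbind, lapply(out, `[[`, "values")),
         ve = vapply(out, `[[`, numeric(1), "var_explained"))
  }
  px <- eg(ds$predictors)
  ry <- eg(ds$responses)
  colnames(px$values) <- names(ds$predictors)
  colnames(ry$values) <- names(ds$responses)
  list(X_pred = px$values, Y_resp = ry$values,
       var_explained = list(predictors = px$ve, responses = ry$ve))
}

#' Analyze a simulated dataset with the g-prior model
#'
#' Runs the regression stage on a `SimDataset`: module eigengenes, prior
#' relatedness from the simulated network, expected-BIC subset selection at
#' weight `mu` (`mu = 0` is the no-prior baseline), and recovery scoring
#' against the ground-truth manifest.
#'
#' @param ds A `SimDataset`.
#' @param mu Prior weight (default 1).
#' @param B Permutations for the correlation test (default 200).
#' @param alpha Coefficient significance level (default 0.05).
#' @param max_size Subset-size cap.
#' @param seed Integer seed.
#' @return List with `fits` ([fit_subnetworks()] output), `recovery`
#'   ([score_recovery()] table), and the relatedness matrix `r`.
#' @export
analyze_sim_dataset <- function(ds, mu = 1, B = 200, alpha = 0.05,
                                max_size = 5, seed = NULL) {
  stopifnot(inherits(ds, "SimDataset"))
  eg <- dataset_eigengenes(ds)
  r <- relatedness_matrix(ds$pred_genes, ds$resp_genes, ds$network)
  fits <- fit_subnetworks(eg$X_pred, eg$Y_resp, r, mu = mu, B = B,
                          max_size = max_size, alpha = alpha, seed = seed)
  list(fits = fits,
       recovery = score_recovery(fits, ds$manifest, alpha = alpha), r = r)
}

#' Score predictor recovery against a ground-truth manifest
#'
#' Compares each response's selected predictor set with the planted set.
#' For responses with a nonempty planted set, `correct` means exact
#' identity. For responses planted with no predictor, `correct` means no
#' selected predictor has a significant coefficient at `alpha` (the subset
#' search always returns at least one predictor; the significance filter is
#' what rules it out).
#'
#' @param fits Named list of `SubnetworkFit` (names = response ids matching
#'   the manifest wiring).
#' @param manifest Manifest list with a `wiring` element.
#' @param alpha Coefficient significance level (default 0.05).
#' @return Data frame: response, selected, true, correct, tp, fp.
#' @export
score_recovery <- function(fits, manifest, alpha = 0.05) {
  wiring <- manifest$wiring
  unknown <- setdiff(names(fits), names(wiring))
  if (length(unknown) > 0) {
    stop("unknown response id(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(names(fits), function(rn) {
    sel <- fits[[rn]]$fit$predictors
    truth <- as.character(wiring[[rn]])
    tp <- length(intersect(sel, truth))
    fp <- length(setdiff(sel, truth))
    correct <- if (length(truth) == 0) {
      all(fits[[rn]]$fit$coef_p >= alpha)
    } else {
      setequal(sel, truth) && fp == 0
    }
    data.frame(response = rn,
               selected = paste(sort(sel), collapse = ","),
               true = paste(sort(truth), collapse = ","),
               correct = correct, tp = tp, fp = fp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full inference pipeline
#'
#' Orchestrates the stages on file inputs: differential networks for both
#' omics layers, module detection by rank-selected symmetric NMF, module
#' eigengenes (tumor samples), g-prior subnetwork regression with mu tuning,
#' and (when a survival table is supplied) prognostic-index survival
#' analysis. All stage outputs are written under `config$out_dir`, sorted by
#' stable keys; two runs with the same config and seed produce identical
#' tables.
#'
#' @param config Named list:
#'   \describe{
#'     \item{expression, expression_conditions}{expression TSV + sidecar}
#'     \item{methylation, methylation_conditions}{methylation TSV + sidecar}
#'     \item{ppi}{interaction edge-list path}
#'     \item{survival}{optional survival CSV}
#'     \item{out_dir}{output directory}
#'     \item{edge_fdr, module_alpha, coef_alpha}{thresholds (all 0.05)}
#'     \item{k_grid}{candidate ranks (default 5:70)}
#'     \item{B}{permutations (default 1000)}
#'     \item{mu_grid}{prior-weight grid (default 0 ... 10)}
#'     \item{max_subset_size}{subset cap (default 5)}
#'     \item{seed}{global seed (default 1)}
#'   }
#' @return List with the differential networks, module sets, eigengenes,
#'   `mu` profile and subnetwork fits, and survival results (or `NULL`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(edge_fdr = 0.05, module_alpha = 0.05, coef_alpha = 0.05,
         k_grid = 5:70, B = 1000,
         mu_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1, 2, 4, 6, 8, 10),
         max_subset_size = 5, seed = 1, out_dir = NULL),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(fn, ...) if (!is.null(out_dir)) fn(...)

  expr <- stage("load", read_omics_matrix(cfg$expression,
                                          cfg$expression_conditions))
  meth <- stage("load", read_omics_matrix(cfg$methylation,
                                          cfg$methylation_conditions))
  ppi <- stage("load", read_interaction_network(cfg$ppi))

  layer <- function(omics, tag, seed_off) {
    dn <- stage(paste0("diffnet/", tag),
                build_differential_network(omics, ppi, fdr = cfg$edge_fdr))
    emit(write_differential_network, dn,
         file.path(out_dir, paste0(tag, "_diffnet.tsv")))
    A <- stage(paste0("similarity/", tag), to_similarity_matrix(dn))
    sel <- stage(paste0("modules/", tag),
                 select_rank(A, cfg$k_grid[cfg$k_grid < nrow(A)],
                             B = cfg$B, alpha = cfg$module_alpha,
                             seed = derive_seed(cfg$seed, seed_off)))
    emit(write_module_table, sel$module_set,
         file.path(out_dir, paste0(tag, "_modules.tsv")))
    sig <- sel$module_set$modules$module[sel$module_set$modules$significant]
    eg <- stage(paste0("eigengene/", tag),
                module_eigengenes(omics, sel$module_set$assignment,
                                  modules = sig))
    emit(write_eigengenes, eg,
         file.path(out_dir, paste0(tag, "_eigengenes.tsv")),
         file.path(out_dir, paste0(tag, "_var_explained.tsv")))
    list(dn = dn, A = A, sel = sel, eg = eg,
         genes = split(names(sel$module_set$assignment),
                       sel$module_set$assignment))
  }
  rl <- layer(expr, "expression", 1)
  pl <- layer(meth, "methylation", 2)

  pred_genes <- pl$genes[as.character(rownames(pl$eg$values))]
  names(pred_genes) <- paste0("x", names(pred_genes))
  resp_genes <- rl$genes[as.character(rownames(rl$eg$values))]
  names(resp_genes) <- paste0("y", names(resp_genes))
  X_pred <- t(pl$eg$values)
  colnames(X_pred) <- names(pred_genes)
  Y_resp <- t(rl$eg$values)
  colnames(Y_resp) <- names(resp_genes)
  r <- stage("relatedness", relatedness_matrix(pred_genes, resp_genes, ppi))
  tuned <- stage("regression",
                 tune_mu(X_pred, Y_resp, r, mu_grid = cfg$mu_grid,
                         B = cfg$B, max_size = cfg$max_subset_size,
                         alpha = cfg$coef_alpha,
                         seed = derive_seed(cfg$seed, 3)))
  emit(function(...) {
    write_subnetworks(tuned$fits,
                      json_path = file.path(out_dir, "subnetworks.json"),
                      tsv_path = file.path(out_dir, "subnetworks.tsv"))
  })

  surv_res <- NULL
  if (!is.null(cfg$survival)) {
    surv <- stage("survival", read_survival_table(cfg$survival))
    surv_res <- stage("survival",
                      survival_stage(tuned$fits, Y_resp, surv,
                                     out_dir = out_dir))
  } else {
    message("no survival table given; survival stage skipped")
  }
  list(expression = rl, methylation = pl, mu = tuned$mu,
       mu_profile = tuned$profile, subnetworks = tuned$fits,
       survival = surv_res, config = cfg)
}

survival_stage <- function(fits, Y_resp, surv, out_dir = NULL) {
  idx <- match(rownames(Y_resp), surv$patient_id)
  if (anyNA(idx)) stop("eigengene samples missing from survival table")
  surv <- surv[idx, , drop = FALSE]
  class(surv) <- c("SurvivalTable", "data.frame")
  rows <- lapply(fits, function(sn) {
    if (!sn$kept) return(NULL)
    E <- cbind(Y_resp[, sn$response, drop = TRUE])
    colnames(E) <- sn$response
    res <- tryCatch({
      beta <- fit_cox(E, surv)
      pis <- prognostic_index(beta, E)
      gr <- risk_groups(pis)
      kl <- km_logrank(gr, surv)
      data.frame(subnetwork = sn$response, cox_beta = beta[[1]],
                 logrank_p = kl$p, flagged = kl$flagged,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    res
  })
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) {
    tab <- tab[order(tab$subnetwork), , drop = FALSE]
    rownames(tab) <- NULL
    if (!is.null(out_dir)) write_tsv(tab, file.path(out_dir, "survival.tsv"))
  }
  tab
}
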
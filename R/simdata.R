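#' Simulation configuration
#'
#' Defaults reproduce the package's reference simulation study: 200
#' samples; four predictor modules of 25 genes with within-module
#' correlation signals (0.3, 0.5, 0.3, 0.5); four response modules of 30
#' genes sharing one correlation signal per dataset (0.3, 0.5 or 0.7);
#' inverse-Wishart covariances with 60 degrees of freedom; planted wiring
#' y1 <- {x1}, y2 <- {x2}, y3 <- {x1, x2}, y4 <- nothing, with association
#' signal `a`; and a random bipartite prior network connecting gene pairs
#' with probability 0.1 inside a true subnetwork and 0.05 elsewhere.
#'
#' @param n Number of samples.
#' @param p Genes per predictor module.
#' @param q Genes per response module.
#' @param c_p Within-module correlation signal per predictor module.
#' @param c_r Response correlation signals, one dataset generated per value.
#' @param df Inverse-Wishart degrees of freedom (must exceed
#'   `max(p, q) + 1`).
#' @param a Association signal between wired predictors and responses.
#' @param wiring Named list response -> character vector of predictor names.
#' @param p_c,p_cn Prior-network edge probabilities within / outside true
#'   subnetworks.
#' @param a_mode `"constant"`: every entry of the wiring matrix equals `a`;
#'   `"uniform"`: entries drawn from `U(a/2, a)`.
#' @param seed Integer seed.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(n = 200, p = 25, q = 30,
                       c_p = c(0.3, 0.5, 0.3, 0.5),
                       c_r = c(0.3, 0.5, 0.7),
                       df = 60, a = 0.1,
                       wiring = list(y1 = "x1", y2 = "x2",
                                     y3 = c("x1", "x2"), y4 = character(0)),
                       p_c = 0.1, p_cn = 0.05,
                       a_mode = c("constant", "uniform"), seed = 1) {
  a_mode <- match.arg(a_mode)
  if (df <= p + 1 || df <= q + 1) {
    stop("df must exceed module dimension + 1 for the inverse-Wishart mean")
  }
  stopifnot(all(c_p >= 0 & c_p < 1), all(c_r >= 0 & c_r < 1),
            p_c >= 0, p_c <= 1, p_cn >= 0, p_cn <= 1, a >= 0)
  structure(list(n = n, p = p, q = q, c_p = c_p, c_r = c_r, df = df, a = a,
                 wiring = wiring, p_c = p_c, p_cn = p_cn, a_mode = a_mode,
                 seed = seed),
            class = "SimConfig")
}

rinvwishart <- function(df, scale) {
  W <- stats::rWishart(1, df, solve(scale))[, , 1]
  solve(W)
}

#' Simulate one correlated module
#'
#' Draws a covariance \eqn{\Sigma} from an inverse-Wishart distribution
#' whose mean is \eqn{(1-c)I + cJ} (unit variances, mean correlation `c`),
#' then `n` i.i.d. multivariate-normal rows with that covariance. The
#' inverse-Wishart scale matrix is \eqn{(df - dim - 1)\,[(1-c)I + cJ]},
#' the scale-matrix convention with mean scale/(df - dim - 1).
#'
#' @param n Number of samples (rows).
#' @param dim Number of variables (genes) in the module.
#' @param c Target mean pairwise correlation, in \[0, 1).
#' @param df Inverse-Wishart degrees of freedom, `> dim + 1`.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return `n x dim` numeric matrix.
#' @export
simulate_module <- function(n, dim, c, df = 60, seed = NULL) {
  if (df <= dim + 1) stop("df must exceed dim + 1")
  with_seed(seed, {
    S <- (df - dim - 1) * ((1 - c) * diag(dim) + c)
    Sigma <- rinvwishart(df, S)
    MASS::mvrnorm(n, rep(0, dim), Sigma)
  })
}

#' Wire a response module to its predictor modules
#'
#' Adds the planted linear dependency \eqn{y^S = y + \sum_{x \in S} x A + E}
#' where `A` is a p-by-q association matrix (all entries `a`, or
#' `U(a/2, a)` draws) and `E` is i.i.d. standard-normal noise.
#'
#' @param y Base response matrix (n x q).
#' @param predictors List of predictor matrices (each n x p); may be empty.
#' @param a Association signal.
#' @param seed Integer seed.
#' @param a_mode `"constant"` (default) or `"uniform"` entries of `A`.
#' @return Wired n x q response matrix.
#' @export
wire_response <- function(y, predictors, a, seed = NULL,
                          a_mode = c("constant", "uniform")) {
  a_mode <- match.arg(a_mode)
  q <- ncol(y); n <- nrow(y)
  with_seed(seed, {
    for (x in predictors) {
      if (nrow(x) != n) stop("sample counts must match")
      A <- if (a_mode == "constant") {
        matrix(a, ncol(x), q)
      } else {
        matrix(stats::runif(ncol(x) * q, a / 2, a), ncol(x), q)
      }
      y <- y + x %*% A
    }
    y + matrix(stats::rnorm(n * q), n, q)
  })
}

#' Simulate a bipartite prior interaction network
#'
#' Connects each predictor-gene/response-gene pair with probability `p_c`
#' when the two modules belong to the same true subnetwork (per `wiring`),
#' and `p_cn` otherwise.
#'
#' @param pred_modules,resp_modules Named lists of gene-id vectors.
#' @param wiring Named list response-module name -> predictor-module names.
#' @param p_c,p_cn Connection probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return An [interaction_network()].
#' @export
simulate_prior_network <- function(pred_modules, resp_modules, wiring,
                                   p_c = 0.1, p_cn = 0.05, seed = NULL) {
  stopifnot(p_c >= 0, p_c <= 1, p_cn >= 0, p_cn <= 1)
  with_seed(seed, {
    rows <- list()
    for (rn in names(resp_modules)) {
      for (pn in names(pred_modules)) {
        prob <- if (pn %in% (wiring[[rn]] %||% character(0))) p_c else p_cn
        if (prob == 0) next
        pairs <- expand.grid(a = pred_modules[[pn]], b = resp_modules[[rn]],
                             stringsAsFactors = FALSE)
        keep <- stats::runif(nrow(pairs)) < prob
        if (any(keep)) rows[[length(rows) + 1]] <- pairs[keep, ]
      }
    }
    if (length(rows) == 0) {
      return(structure(list(edges = data.frame(a = character(0),
                                               b = character(0),
                                               stringsAsFactors = FALSE),
                            nodes = character(0)),
                       class = "InteractionNetwork"))
    }
    interaction_network(do.call(rbind, rows))
  })
}

sim_gene_ids <- function(prefix, module, size) {
  paste0(prefix, module, "_g", seq_len(size))
}

#' Generate one simulated study dataset
#'
#' One dataset = four predictor modules, four response modules sharing the
#' dataset's response correlation `c_r`, the planted wiring, and the random
#' bipartite prior network, with a ground-truth manifest sufficient to score
#' recovery.
#'
#' @param config A [sim_config()].
#' @param c_r Response correlation signal for this dataset.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List of class `SimDataset` with `predictors` (named list of
#'   n x p matrices), `responses` (named list of wired n x q matrices),
#'   `pred_genes`/`resp_genes` (gene-id lists), `network`, and `manifest`
#'   (wiring, signal, sizes, seed).
#' @export
simulate_dataset <- function(config, c_r, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  kp <- length(config$c_p)
  preds <- lapply(seq_len(kp), function(i) {
    simulate_module(config$n, config$p, config$c_p[i], config$df,
                    seed = derive_seed(seed, i))
  })
  names(preds) <- paste0("x", seq_len(kp))
  kr <- length(config$wiring)
  resps <- lapply(seq_len(kr), function(i) {
    base <- simulate_module(config$n, config$q, c_r, config$df,
                            seed = derive_seed(seed, 100 + i))
    wire_response(base, preds[config$wiring[[i]]], config$a,
                  seed = derive_seed(seed, 200 + i), a_mode = config$a_mode)
  })
  names(resps) <- names(config$wiring)
  pred_genes <- lapply(names(preds), function(nm) {
    sim_gene_ids("m", nm, config$p)
  })
  names(pred_genes) <- names(preds)
  resp_genes <- lapply(names(resps), function(nm) {
    sim_gene_ids("e", nm, config$q)
  })
  names(resp_genes) <- names(resps)
  net <- simulate_prior_network(pred_genes, resp_genes, config$wiring,
                                config$p_c, config$p_cn,
                                seed = derive_seed(seed, 300))
  structure(list(predictors = preds, responses = resps,
                 pred_genes = pred_genes, resp_genes = resp_genes,
                 network = net,
                 manifest = list(wiring = config$wiring, a = config$a,
                                 c_r = c_r, n = config$n, p = config$p,
                                 q = config$q, seed = seed)),
            class = "SimDataset")
}

#' Generate the full simulation study
#'
#' One dataset per response-correlation value in `config$c_r`. With `dir`
#' set, every dataset is written in the pipeline's native input formats:
#' `methylation.tsv` / `expression.tsv` (gene-by-sample TSV),
#' `conditions.tsv`, `network.tsv` (edge list), and `manifest.json`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (one subdirectory per dataset).
#' @return Named list of `SimDataset` bundles (names `dataset1`, ...).
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  out <- lapply(seq_along(config$c_r), function(d) {
    simulate_dataset(config, config$c_r[d],
                     seed = derive_seed(config$seed, 10000 * d))
  })
  names(out) <- paste0("dataset", seq_along(config$c_r))
  if (!is.null(dir)) {
    for (nm in names(out)) {
      write_sim_dataset(out[[nm]], file.path(dir, nm))
    }
  }
  out
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' @param ds A `SimDataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "SimDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- paste0("s", seq_len(nrow(ds$predictors[[1]])))
  stack <- function(mats, genes) {
    M <- do.call(cbind, mats)            # n x total genes
    M <- t(M)
    rownames(M) <- unlist(genes)
    colnames(M) <- samples
    M
  }
  meth <- stack(ds$predictors, ds$pred_genes)
  expr <- stack(ds$responses, ds$resp_genes)
  write_tsv(data.frame(gene = rownames(meth), meth, check.names = FALSE),
            file.path(dir, "methylation.tsv"))
  write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample = samples, condition = "tumor"),
            file.path(dir, "conditions.tsv"))
  utils::write.table(ds$network$edges, file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  manifest <- ds$manifest
  manifest$pred_genes <- ds$pred_genes
  manifest$resp_genes <- ds$resp_genes
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset bundle written by [write_sim_dataset()]
#'
#' @param dir Bundle directory.
#' @return A `SimDataset` (matrices reassembled per module).
#' @export
read_sim_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  manifest$wiring <- lapply(manifest$wiring, as.character)
  load_layer <- function(file, genes) {
    tab <- utils::read.delim(file.path(dir, file), check.names = FALSE)
    M <- as.matrix(tab[, -1, drop = FALSE])
    rownames(M) <- as.character(tab[[1]])
    lapply(genes, function(gs) t(M[gs, , drop = FALSE]))
  }
  pred_genes <- lapply(manifest$pred_genes, as.character)
  resp_genes <- lapply(manifest$resp_genes, as.character)
  structure(list(
    predictors = load_layer("methylation.tsv", pred_genes),
    responses = load_layer("expression.tsv", resp_genes),
    pred_genes = pred_genes, resp_genes = resp_genes,
    network = read_interaction_network(file.path(dir, "network.tsv")),
    manifest = manifest[c("wiring", "a", "c_r", "n", "p", "q", "seed")]),
    class = "SimDataset")
}

#' Simulate survival times driven by eigengenes
#'
#' Exponential event times with hazard
#' \eqn{\lambda_i = \lambda_0 \exp(\beta^T E_i)} and independent exponential
#' censoring, for testing the survival stage without clinical data.
#'
#' @param eigengenes Per-patient values: vector or patient-by-module matrix.
#' @param beta_true True log-hazard coefficient(s).
#' @param baseline_rate Baseline hazard rate (> 0, default 0.001 per day).
#' @param censor_rate Censoring hazard rate (> 0, default 0.0005).
#' @param seed Integer seed.
#' @return A [survival_table()].
#' @export
simulate_survival <- function(eigengenes, beta_true, baseline_rate = 0.001,
                              censor_rate = 5e-4, seed = NULL) {
  if (baseline_rate <= 0 || censor_rate <= 0) stop("rates must be positive")
  E <- as.matrix(eigengenes)
  lp <- as.numeric(E %*% beta_true)
  with_seed(seed, {
    tev <- stats::rexp(length(lp), rate = baseline_rate * exp(lp))
    tc <- stats::rexp(length(lp), rate = censor_rate)
    survival_table(rownames(E) %||% paste0("pt", seq_along(lp)),
                   pmin(tev, tc), as.integer(tev <= tc))
  })
}
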
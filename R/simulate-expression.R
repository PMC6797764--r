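# Synthetic expression generator: planted co-expression modules driven by
# per-sample latent factors, plus a trait constructed to correlate with the
# factors at specified Pearson r.

#' Parameters for the expression simulator
#'
#' @param module_sizes integer vector, genes per planted module.
#' @param n_samples number of samples.
#' @param trait_correlations Pearson r in `[-1, 1]`, one per module; the
#'   trait is built as `sum(r_m * f_m) + sqrt(1 - sum(r_m^2)) * noise`, so
#'   `sum(r^2)` must not exceed 1.
#' @param noise_sd standard deviation of gene-level noise (default 0.5).
#' @param background_fraction fraction of genes belonging to no module
#'   (default 0.5); used to size the background when `n_genes` is omitted.
#' @param n_genes total genes; default derived from `module_sizes` and
#'   `background_fraction`.
#' @param seed integer seed.
#' @return object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(module_sizes, n_samples,
                                  trait_correlations = rep(0, length(module_sizes)),
                                  noise_sd = 0.5, background_fraction = 0.5,
                                  n_genes = NULL, seed = 1L) {
  stopifnot(all(module_sizes >= 1), n_samples >= 3,
            length(trait_correlations) == length(module_sizes),
            all(abs(trait_correlations) <= 1), noise_sd >= 0,
            background_fraction >= 0, background_fraction < 1)
  if (sum(trait_correlations^2) > 1) {
    stop("sum of squared trait correlations exceeds 1")
  }
  if (is.null(n_genes)) {
    n_genes <- ceiling(sum(module_sizes) / (1 - background_fraction))
  }
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  structure(list(module_sizes = as.integer(module_sizes),
                 n_samples = as.integer(n_samples),
                 trait_correlations = trait_correlations,
                 noise_sd = noise_sd, n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "expression_sim_params")
}

#' Simulate an expression matrix with planted modules
#'
#' Each module `m` gets a standard-normal latent factor `f_m` per sample;
#' its genes are `baseline + loading * f_m + Normal(0, noise_sd)` with
#' positive loadings in `[0.8, 1.2]`. Background genes are baseline plus
#' unit-variance noise. Values are on a log2-like abundance scale with
#' gene baselines in `[4, 8]`, floored at 0. The trait is a standardized
#' combination of the factors with the requested expected correlations.
#'
#' @param params an [expression_sim_params()] object.
#' @return list with `expr` (genes x samples matrix, dimnames set) and
#'   `truth`: `module_labels` (0 = background), `latent_factors`
#'   (modules x samples), `trait` (per sample), `loadings`.
#' @export
#' @examples
#' p <- expression_sim_params(module_sizes = 30, n_samples = 20,
#'                            trait_correlations = 0.6, seed = 3)
#' sim <- simulate_expression(p)
#' dim(sim$expr)
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  with_seed(params$seed, {
    ng <- params$n_genes; ns <- params$n_samples
    sizes <- params$module_sizes; nm <- length(sizes)
    labels <- integer(ng)
    labels[seq_len(sum(sizes))] <- rep(seq_len(nm), sizes)
    f <- matrix(stats::rnorm(nm * ns), nm, ns)
    baseline <- stats::runif(ng, 4, 8)
    loadings <- numeric(ng)
    expr <- matrix(stats::rnorm(ng * ns), ng, ns)  # background noise, sd 1
    for (m in seq_len(nm)) {
      idx <- which(labels == m)
      loadings[idx] <- stats::runif(length(idx), 0.8, 1.2)
      expr[idx, ] <- loadings[idx] %o% f[m, ] +
        matrix(stats::rnorm(length(idx) * ns, 0, params$noise_sd),
               length(idx), ns)
    }
    expr <- pmax(expr + baseline, 0)
    dimnames(expr) <- list(sprintf("gene%05d", seq_len(ng)),
                           sprintf("sample%03d", seq_len(ns)))
    r <- params$trait_correlations
    resid_sd <- sqrt(max(0, 1 - sum(r^2)))
    trait <- as.numeric(crossprod(f, r)) + stats::rnorm(ns, 0, resid_sd)
    names(trait) <- colnames(expr)
    list(expr = expr,
         truth = list(module_labels = labels, latent_factors = f,
                      trait = trait, loadings = loadings))
  })
}

#' Read / write expression TSV
#'
#' Tab-separated, first column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @return `read_expression` returns a genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression
#' @param expr genes x samples matrix.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
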
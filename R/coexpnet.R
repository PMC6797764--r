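# Signed weighted co-expression network: biweight midcorrelation, soft
# thresholding, topological overlap, module detection by average-linkage
# clustering with a static cut and eigengene merging, and module-trait
# correlation with BH-FDR.

#' Network construction configuration
#'
#' @param correlation `"bicor"` (biweight midcorrelation, robust default)
#'   or `"pearson"`.
#' @param soft_power soft-threshold exponent beta (default 10, chosen by
#'   the scale-free topology criterion).
#' @param min_module_size smallest branch kept as a module (default 30
#'   genes; smaller branches go to the unassigned `"grey"` label).
#' @param merge_height eigengene dissimilarity `1 - cor` below which
#'   modules are merged (default 0.30).
#' @param cut_height static tree-cut height on the TOM dissimilarity
#'   dendrogram (default 0.99).
#' @param kme_min module-membership cleanup threshold: after merging,
#'   genes whose correlation with their module's eigengene falls below
#'   this value are returned to grey (default 0.3; requires expression
#'   data at detection time).
#' @param min_expressed_samples gene filter: keep genes expressed (> 0) in
#'   strictly more than this many samples (default 10).
#' @param log_transform apply `log2(x + 1)` to abundances before
#'   correlation (default `TRUE`; set `FALSE` for data already on a log
#'   scale).
#' @return object of class `network_config`.
#' @export
network_config <- function(correlation = c("bicor", "pearson"),
                           soft_power = 10, min_module_size = 30,
                           merge_height = 0.30, cut_height = 0.99,
                           kme_min = 0.3, min_expressed_samples = 10,
                           log_transform = TRUE) {
  correlation <- match.arg(correlation)
  stopifnot(soft_power >= 1, min_module_size >= 2,
            merge_height > 0, merge_height < 1,
            cut_height > 0, cut_height <= 1,
            kme_min >= 0, kme_min < 1, min_expressed_samples >= 0)
  structure(list(correlation = correlation, soft_power = soft_power,
                 min_module_size = min_module_size,
                 merge_height = merge_height, cut_height = cut_height,
                 kme_min = kme_min,
                 min_expressed_samples = min_expressed_samples,
                 log_transform = isTRUE(log_transform)),
            class = "network_config")
}

#' Filter genes by expression presence
#'
#' Keeps genes with abundance strictly greater than zero in strictly more
#' than `min_samples` samples.
#'
#' @param expr genes x samples matrix.
#' @param min_samples presence threshold (default 10).
#' @return the filtered matrix.
#' @export
filter_genes <- function(expr, min_samples = 10) {
  keep <- rowSums(expr > 0) > min_samples
  if (!any(keep)) stop("no genes pass the expression filter")
  expr[keep, , drop = FALSE]
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation between gene rows: observations are weighted by
#' `w = (1 - u^2)^2` for `|u| < 1` with `u = (x - median) / (9 * mad)`
#' (`mad` unscaled), then correlated as weighted deviations from the
#' median. Genes with zero median absolute deviation fall back to Pearson
#' (mean-centered) with a warning. The matrix is symmetric with unit
#' diagonal.
#'
#' @param expr genes x samples matrix (at least 4 samples).
#' @return genes x genes correlation matrix.
#' @export
bicor_matrix <- function(expr) {
  if (ncol(expr) < 4) stop("need at least 4 samples")
  n <- ncol(expr)
  med <- apply(expr, 1, stats::median)
  madu <- apply(abs(expr - med), 1, stats::median)
  centered <- expr - med
  u <- centered / (9 * madu)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  v <- centered * w
  fallback <- madu == 0
  if (any(fallback)) {
    warning(sum(fallback), " gene(s) with zero MAD fell back to Pearson")
    cm <- expr[fallback, , drop = FALSE]
    v[fallback, ] <- cm - rowMeans(cm)
  }
  norms <- sqrt(rowSums(v^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " constant gene(s); correlations set to 0")
    norms[zero] <- 1
  }
  v <- v / norms
  cmat <- tcrossprod(v)
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  if (any(zero)) {
    cmat[zero, ] <- 0
    cmat[, zero] <- 0
    diag(cmat) <- 1
  }
  cmat
}

#' Correlation matrix per configuration
#'
#' @param expr genes x samples matrix.
#' @param config a [network_config()].
#' @return genes x genes correlation matrix ([bicor_matrix()] or Pearson).
#' @export
correlation_matrix <- function(expr, config = network_config()) {
  if (config$correlation == "bicor") bicor_matrix(expr) else {
    cmat <- stats::cor(t(expr))
    cmat[is.na(cmat)] <- 0
    diag(cmat) <- 1
    cmat
  }
}

#' Signed soft-threshold adjacency
#'
#' `a = ((1 + cor) / 2)^beta`, mapping correlation -1 to 0 and +1 to 1 so
#' that anti-correlated genes are not connected. The diagonal is set to 0
#' for connectivity computations.
#'
#' @param cor_matrix correlation matrix with entries in `[-1, 1]`.
#' @param beta soft-threshold exponent (default 10).
#' @return adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
#' @examples
#' signed_adjacency(matrix(c(1, 0, 0, 1), 2), beta = 10)[1, 2]  # 0.5^10
signed_adjacency <- function(cor_matrix, beta = 10) {
  if (any(abs(cor_matrix) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  a <- ((1 + cor_matrix) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Bins node connectivity `k = rowSums(adjacency)`, regresses
#' `log10(frequency)` on `log10(mean k)` over occupied bins, and returns
#' the fit R-squared signed by `-sign(slope)`, so that positive values
#' indicate the decaying degree distribution expected of a scale-free
#' network.
#'
#' @param adjacency adjacency matrix, or a precomputed connectivity vector.
#' @param n_bins number of equal-width connectivity bins (default 10).
#' @return signed R-squared of the log-log fit.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- if (is.matrix(adjacency)) rowSums(adjacency) else as.numeric(adjacency)
  if (length(k) < 20) stop("need at least 20 nodes")
  if (diff(range(k)) < .Machine$double.eps^0.5) {
    stop("degenerate connectivity: all nodes have equal k")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) stop("too few occupied bins for a log-log fit")
  fit <- stats::lm(log10(freq[keep] / length(k)) ~ log10(mean_k[keep]))
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits are legitimate
  slope <- stats::coef(fit)[2]
  unname(r2 * -sign(slope))
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbors and `k` the node
#' connectivity; `TOM_ii = 1`. High overlap means two genes share much of
#' their network neighborhood, not merely a strong direct edge.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` (diagonal ignored).
#' @return list with `similarity` and `dissimilarity = 1 - similarity`.
#' @export
tom_matrix <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  list(similarity = tom, dissimilarity = 1 - tom)
}

# Standard module color sequence (largest module first).
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("module%02d", seq_len(n - length(base)) + length(base)))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' branches taken by a static cut at `cut_height`; branches smaller than
#' `min_module_size` are assigned to `"grey"` (unassigned). When the
#' expression matrix is supplied, modules whose eigengenes are closer than
#' `merge_height` on the `1 - cor` scale are merged iteratively. Module
#' labels are color-style names in decreasing size order.
#'
#' @param dissimilarity square TOM dissimilarity matrix.
#' @param config a [network_config()].
#' @param expr optional genes x samples matrix (same row order) enabling
#'   eigengene-based merging.
#' @return object of class `module_assignment`: list with `labels`
#'   (character per gene), `sizes`, and the `hclust` tree.
#' @export
detect_modules <- function(dissimilarity, config = network_config(),
                           expr = NULL) {
  n <- nrow(dissimilarity)
  stopifnot(n == ncol(dissimilarity))
  gene_ids <- rownames(dissimilarity) %||% sprintf("gene%05d", seq_len(n))
  if (n < config$min_module_size) {
    labels <- rep("grey", n)
    names(labels) <- gene_ids
    return(structure(list(labels = labels, sizes = c(grey = n), tree = NULL),
                     class = "module_assignment"))
  }
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  cl <- stats::cutree(tree, h = config$cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < config$min_module_size])] <- 0L

  if (!is.null(expr)) {
    if (length(unique(cl[cl != 0])) > 1) {
      cl <- merge_close_modules(cl, expr, config$merge_height)
    }
    cl <- kme_cleanup(cl, expr, config$kme_min, config$min_module_size)
  }

  kept <- sort(table(cl[cl != 0]), decreasing = TRUE)
  colors <- module_colors(length(kept))
  labels <- rep("grey", n)
  for (i in seq_along(kept)) {
    labels[cl == as.integer(names(kept)[i])] <- colors[i]
  }
  names(labels) <- gene_ids
  structure(list(labels = labels,
                 sizes = sort(table(labels), decreasing = TRUE),
                 tree = tree),
            class = "module_assignment")
}

# Iteratively merge modules whose eigengene dissimilarity (1 - cor) falls
# below merge_height.
merge_close_modules <- function(cl, expr, merge_height) {
  repeat {
    ids <- sort(unique(cl[cl != 0]))
    if (length(ids) < 2) return(cl)
    mes <- vapply(ids, function(m)
      module_eigengene(expr, which(cl == m))$me, numeric(ncol(expr)))
    d <- 1 - stats::cor(mes)
    diag(d) <- Inf
    if (min(d) >= merge_height) return(cl)
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    keep <- ids[pair[which.max(tabulate(factor(cl, levels = ids))[pair])]]
    drop <- setdiff(ids[pair], keep)[1]
    cl[cl == drop] <- keep
  }
}

# Return genes weakly correlated with their module eigengene to grey, and
# dissolve modules that fall below the minimum size afterwards.
kme_cleanup <- function(cl, expr, kme_min, min_module_size) {
  if (kme_min <= 0) return(cl)
  repeat {
    changed <- FALSE
    for (m in sort(unique(cl[cl != 0]))) {
      idx <- which(cl == m)
      if (length(idx) < 2) { cl[idx] <- 0L; changed <- TRUE; next }
      me <- module_eigengene(expr, idx)$me
      kme <- suppressWarnings(as.numeric(stats::cor(t(expr[idx, , drop = FALSE]), me)))
      weak <- is.na(kme) | kme < kme_min
      if (any(weak)) { cl[idx[weak]] <- 0L; changed <- TRUE }
      idx <- which(cl == m)
      if (length(idx) > 0 && length(idx) < min_module_size) {
        cl[idx] <- 0L; changed <- TRUE
      }
    }
    if (!changed) return(cl)
  }
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("Module assignment:", length(x$labels), "genes,",
      sum(names(x$sizes) != "grey"), "modules\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression:
#' genes are scaled to mean 0, sd 1 across samples, and the eigengene is
#' the unit-norm first right singular vector (per-sample scores),
#' sign-aligned to correlate positively with the module's average
#' standardized expression. Constant genes are dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @param genes row indices or names of the module's genes (at least 2).
#' @return list with `me` (per-sample scores, named), `var_explained`
#'   (fraction of module variance captured).
#' @export
module_eigengene <- function(expr, genes) {
  x <- expr[genes, , drop = FALSE]
  if (nrow(x) < 2) stop("module must contain at least 2 genes")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from the eigengene")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 non-constant genes in the module")
  }
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  me <- sv$v[, 1]
  if (stats::cor(me, colMeans(xs)) < 0) me <- -me
  names(me) <- colnames(expr)
  list(me = me, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every module of an assignment
#'
#' @param expr genes x samples matrix (rows matching the assignment).
#' @param assignment a [detect_modules()] result.
#' @return samples x modules matrix of eigengene scores (grey excluded).
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- setdiff(names(assignment$sizes), "grey")
  if (!length(mods)) stop("no modules to summarize")
  mes <- vapply(mods, function(m)
    module_eigengene(expr, which(assignment$labels == m))$me,
    numeric(ncol(expr)))
  rownames(mes) <- colnames(expr)
  mes
}

#' Module-trait correlation table
#'
#' Pearson correlation between each module eigengene and each trait, with
#' two-sided p-values and Benjamini-Hochberg q-values computed within each
#' trait across modules.
#'
#' @param mes samples x modules eigengene matrix.
#' @param traits per-sample trait values: vector, matrix or data frame
#'   (rows aligned with `mes`).
#' @return data frame with `module`, `trait`, `r`, `p`, `q`.
#' @export
module_trait_correlation <- function(mes, traits) {
  if (is.vector(traits)) traits <- data.frame(trait = traits)
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(mes)) stop("samples misaligned between MEs and traits")
  out <- list()
  for (tr in names(traits)) {
    tv <- traits[[tr]]
    if (stats::sd(tv) == 0) stop("trait '", tr, "' has zero variance")
    rows <- lapply(colnames(mes), function(m) {
      ht <- stats::cor.test(mes[, m], tv)
      data.frame(module = m, trait = tr,
                 r = unname(ht$estimate), p = ht$p.value)
    })
    block <- do.call(rbind, rows)
    block$q <- bh_fdr(block$p)
    out[[tr]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene significance and module membership
#'
#' Module membership `MM(g, m)` is the correlation between gene `g`'s
#' expression and module `m`'s eigengene; gene significance `GS(g)` is the
#' absolute correlation between the gene and the trait.
#'
#' @param expr genes x samples matrix.
#' @param mes samples x modules eigengene matrix.
#' @param trait per-sample trait vector.
#' @return list with `mm` (genes x modules matrix) and `gs` (named vector).
#' @export
gene_significance_membership <- function(expr, mes, trait) {
  if (length(trait) != ncol(expr)) stop("trait misaligned with samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) warning(sum(sds == 0), " constant gene(s): MM/GS set NA")
  xt <- t(expr)
  mm <- suppressWarnings(stats::cor(xt, mes))
  gs <- abs(suppressWarnings(stats::cor(xt, trait))[, 1])
  list(mm = mm, gs = gs)
}

#' Run the full co-expression stage
#'
#' Convenience wrapper: gene filter, optional log2 transform, correlation,
#' signed adjacency, TOM, module detection with eigengene merging, module
#' eigengenes, and (when traits are given) the module-trait table.
#'
#' @param expr genes x samples abundance matrix.
#' @param traits optional per-sample traits (vector or data frame).
#' @param config a [network_config()].
#' @return list with `expr` (filtered/transformed), `assignment`, `mes`,
#'   `module_trait` (or `NULL`), `scale_free_r2`.
#' @export
coexpression_network <- function(expr, traits = NULL,
                                 config = network_config()) {
  expr <- filter_genes(expr, config$min_expressed_samples)
  analysis <- if (config$log_transform) log2(expr + 1) else expr
  cmat <- correlation_matrix(analysis, config)
  adj <- signed_adjacency(cmat, config$soft_power)
  sf <- tryCatch(scale_free_fit(adj), error = function(e) NA_real_)
  tom <- tom_matrix(adj)
  assignment <- detect_modules(tom$dissimilarity, config, expr = analysis)
  has_modules <- any(names(assignment$sizes) != "grey")
  mes <- if (has_modules) module_eigengenes(analysis, assignment) else NULL
  mt <- if (!is.null(mes) && !is.null(traits))
    module_trait_correlation(mes, traits) else NULL
  list(expr = analysis, assignment = assignment, mes = mes,
       module_trait = mt, scale_free_r2 = sf)
}
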
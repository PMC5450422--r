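# Group statistics (ANOVA + Kruskal-Wallis, mean +/- s.e., 95% CI overlap),
# k-means and feedforward-network classification of leaflet groups, genetic
# algorithm feature-subset selection, and 3D morphospace ellipsoids.

#' Compare one parameter across leaflet groups
#'
#' Most blade and margin parameters are not normally distributed, so groups
#' are compared with both one-way ANOVA and the Kruskal-Wallis test. Each
#' group is summarized as mean +/- standard error with dispersion sd/mean;
#' a pair of groups is flagged significantly different when their 95%
#' confidence intervals of the mean do not overlap. No multiple-testing
#' correction is applied across parameters (tests are reported per
#' parameter).
#'
#' @param table data.frame feature table
#' @param parameter column name to compare
#' @param groups column name holding group labels (default "group"), or a
#'   vector of labels of length nrow(table)
#' @return object of class `group_comparison`: list(summary data.frame,
#'   anova_p, kruskal_p, significant pair matrix)
#' @export
compare_groups <- function(table, parameter, groups = "group") {
  v <- table[[parameter]]
  if (is.null(v)) stop("parameter not found: ", parameter)
  gl <- if (length(groups) == 1 && is.character(groups)) table[[groups]] else groups
  gl <- factor(gl)
  ok <- is.finite(v)
  v <- v[ok]; gl <- droplevels(factor(gl[ok]))
  if (nlevels(gl) < 2) stop("need at least two groups")
  if (any(tabulate(gl) < 2)) stop("every group needs n >= 2")
  av <- stats::aov(v ~ gl)
  anova_p <- summary(av)[[1]][["Pr(>F)"]][1]
  kruskal_p <- stats::kruskal.test(v, gl)$p.value
  sm <- do.call(rbind, lapply(levels(gl), function(g) {
    x <- v[gl == g]
    se <- stats::sd(x) / sqrt(length(x))
    ci <- stats::qt(0.975, length(x) - 1) * se
    data.frame(group = g, n = length(x), mean = mean(x), se = se,
               ci_lo = mean(x) - ci, ci_hi = mean(x) + ci,
               dispersion = stats::sd(x) / mean(x))
  }))
  k <- nlevels(gl)
  sig <- matrix(FALSE, k, k, dimnames = list(levels(gl), levels(gl)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    disjoint <- sm$ci_lo[i] > sm$ci_hi[j] || sm$ci_lo[j] > sm$ci_hi[i]
    sig[i, j] <- sig[j, i] <- disjoint
  }
  structure(list(parameter = parameter, summary = sm,
                 anova_p = anova_p, kruskal_p = kruskal_p, significant = sig),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: ANOVA p = %.3g, Kruskal-Wallis p = %.3g\n",
              x$parameter, x$anova_p, x$kruskal_p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# z-score standardization with stored parameters (fit on training data)
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(mu = mu, sd = sg)
}
standardize_apply <- function(X, fit) scale(X, center = fit$mu, scale = fit$sd)

# accuracy-maximizing assignment of predicted clusters to true groups;
# exhaustive over permutations for k <= 8, greedy beyond
match_clusters <- function(conf) {
  k <- nrow(conf)
  stopifnot(k == ncol(conf))
  if (k <= 8) {
    perms <- permutations_of(seq_len(k))
    best <- 0; bestp <- seq_len(k)
    for (p in perms) {
      s <- sum(conf[cbind(seq_len(k), p)])
      if (s > best) { best <- s; bestp <- p }
    }
    bestp
  } else {
    # greedy: repeatedly take the largest remaining cell
    p <- rep(NA_integer_, k)
    cc <- conf
    for (step in seq_len(k)) {
      ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      p[ij[1]] <- ij[2]
      cc[ij[1], ] <- -1; cc[, ij[2]] <- -1
    }
    p
  }
}
permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (rest in permutations_of(v[-i]))
    out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# assemble the standard classification result object
classification_result <- function(method, features, conf, accuracy, n_repeats, seed,
                                  accuracy_pooled = NULL) {
  structure(list(method = method, feature_subset = features,
                 confusion_matrix = conf, accuracy = accuracy,
                 accuracy_pooled = if (is.null(accuracy_pooled)) accuracy else accuracy_pooled,
                 n_repeats = n_repeats, seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s on {%s}: accuracy %.1f%% (%d repeat%s, seed %d)\n",
              x$method, paste(x$feature_subset, collapse = ", "),
              100 * x$accuracy, x$n_repeats, if (x$n_repeats > 1) "s" else "", x$seed))
  print(x$confusion_matrix)
  invisible(x)
}

#' k-means classification of leaflet groups
#'
#' Runs k-means on the z-scored selected features and scores the clustering
#' against the true group labels through the accuracy-maximizing
#' cluster-to-group assignment. Accuracy is the fraction of correctly
#' classified samples; the confusion matrix has input groups as rows and
#' assigned groups as columns.
#'
#' @param table feature data.frame with a group label column
#' @param features character vector of 3-4 feature column names
#' @param k number of clusters (defaults to the number of groups)
#' @param seed RNG seed (k-means initialization)
#' @param groups label column name or label vector
#' @param nstart k-means restarts
#' @return a `classification_result`
#' @export
kmeans_classify <- function(table, features, k = NULL, seed = 1,
                            groups = "group", nstart = 10) {
  gl <- factor(if (length(groups) == 1 && is.character(groups)) table[[groups]] else groups)
  X <- as.matrix(table[, features, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; gl <- droplevels(gl[ok])
  if (is.null(k)) k <- nlevels(gl)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds the number of samples")
  Z <- standardize_apply(X, standardize_fit(X))
  Z[!is.finite(Z)] <- 0
  cl <- if (nrow(unique(Z)) < k) {
    # degenerate feature space: fewer distinct points than clusters; the
    # best constant assignment puts everything in one cluster
    rep(1L, nrow(Z))
  } else {
    with_seed(seed, stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 50))$cluster
  }
  conf <- table(true = gl, cluster = factor(cl, levels = seq_len(k)))
  conf <- unclass(as.matrix(conf))
  kk <- max(nlevels(gl), k)
  sq <- matrix(0, kk, kk)
  sq[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  p <- match_clusters(sq)
  # reorder cluster columns so the matched cluster sits on the diagonal
  mapped <- sq[, p, drop = FALSE][seq_len(nlevels(gl)), seq_len(nlevels(gl)), drop = FALSE]
  dimnames(mapped) <- list(input = levels(gl), assigned = levels(gl))
  acc <- sum(diag(mapped)) / sum(mapped)
  classification_result("kmeans", features, mapped, acc, 1L, seed)
}

#' Feedforward neural-network classification with repeated 75/25 splits
#'
#' A single-hidden-layer feedforward network (3-15 hidden units) is trained
#' on a stratified random 75% of the samples and scored on the held-out
#' 25%; the split/train/score cycle is repeated `n_repeats` times (default
#' 30) with different splits. Features are z-scored with training-set
#' parameters. Reported accuracy is the mean held-out accuracy over
#' repeats; the pooled-confusion accuracy is also recorded, and the
#' aggregated confusion matrix counts all held-out classifications.
#'
#' @param table feature data.frame
#' @param features 3-4 feature column names
#' @param hidden_units hidden layer size (3-15)
#' @param n_repeats number of random splits (default 30)
#' @param seed RNG seed
#' @param groups label column name or label vector
#' @param decay,maxit nnet regularization and iteration cap
#' @return a `classification_result`
#' @export
ann_classify <- function(table, features, hidden_units = 8, n_repeats = 30,
                         seed = 1, groups = "group", decay = 5e-3, maxit = 200) {
  gl <- factor(if (length(groups) == 1 && is.character(groups)) table[[groups]] else groups)
  X <- as.matrix(table[, features, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; gl <- droplevels(gl[ok])
  sizes <- tabulate(gl)
  if (any(sizes < 4)) stop("group too small for a stratified 75/25 split: ",
                           paste(levels(gl)[sizes < 4], collapse = ", "))
  k <- nlevels(gl)
  conf <- matrix(0, k, k, dimnames = list(input = levels(gl), assigned = levels(gl)))
  accs <- numeric(n_repeats)
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      test_idx <- unlist(lapply(levels(gl), function(g) {
        ii <- which(gl == g)
        sample(ii, max(1, round(length(ii) * 0.25)))
      }))
      tr <- setdiff(seq_along(gl), test_idx)
      fit <- standardize_fit(X[tr, , drop = FALSE])
      Ztr <- standardize_apply(X[tr, , drop = FALSE], fit)
      Zte <- standardize_apply(X[test_idx, , drop = FALSE], fit)
      net <- nnet::nnet(Ztr, nnet::class.ind(gl[tr]), size = hidden_units,
                        decay = decay, maxit = maxit, softmax = TRUE, trace = FALSE)
      pred <- factor(levels(gl)[max.col(stats::predict(net, Zte))], levels = levels(gl))
      accs[r] <- mean(pred == gl[test_idx])
      conf <- conf + unclass(table(gl[test_idx], pred))
    }
  })
  res <- classification_result("ann", features, conf, mean(accs), n_repeats, seed,
                               accuracy_pooled = sum(diag(conf)) / sum(conf))
  res$accuracy_per_repeat <- accs
  res
}

#' Genetic-algorithm selection of discriminative feature subsets
#'
#' Searches subsets of 3 or 4 parameters whose classification accuracy (by
#' k-means or the feedforward network) is maximal: individuals are feature
#' subsets, fitness is classification accuracy, with tournament selection,
#' uniform membership crossover, single-feature swap mutation and elitism.
#' All evaluated subsets reaching `min_accuracy` are returned ranked by
#' accuracy and de-duplicated; an empty result is not an error.
#'
#' @param table feature data.frame
#' @param candidate_features columns to search over (default: all numeric
#'   columns except the label)
#' @param classifier `"kmeans"` or `"ann"`
#' @param subset_size 3 or 4
#' @param min_accuracy retention threshold (default 0.85)
#' @param seed RNG seed
#' @param groups label column name or label vector
#' @param pop_size,generations,elite,tournament,p_mut GA controls
#' @param ann_repeats repeats used inside the ANN fitness evaluation
#' @return data.frame with columns feature_1..feature_k, accuracy; ranked
#' @export
ga_select_features <- function(table, candidate_features = NULL,
                               classifier = c("kmeans", "ann"),
                               subset_size = 3, min_accuracy = 0.85, seed = 1,
                               groups = "group", pop_size = 40, generations = 60,
                               elite = 2, tournament = 3, p_mut = 0.3,
                               ann_repeats = 5) {
  classifier <- match.arg(classifier)
  if (is.null(candidate_features)) {
    num <- vapply(table, is.numeric, logical(1))
    candidate_features <- setdiff(names(table)[num], groups)
  }
  m <- length(candidate_features)
  if (m < subset_size) stop("fewer candidate features than the subset size")
  fitness_cache <- new.env(parent = emptyenv())
  eval_subset <- function(ss) {
    key <- paste(sort(ss), collapse = "|")
    if (!is.null(fitness_cache[[key]])) return(fitness_cache[[key]])
    feats <- candidate_features[sort(ss)]
    acc <- if (classifier == "kmeans")
      kmeans_classify(table, feats, seed = seed, groups = groups)$accuracy
    else
      ann_classify(table, feats, n_repeats = ann_repeats, seed = seed,
                   groups = groups)$accuracy
    fitness_cache[[key]] <- acc
    acc
  }
  with_seed(seed, {
    pop <- replicate(pop_size, sort(sample.int(m, subset_size)), simplify = FALSE)
    for (gen in seq_len(generations)) {
      fit <- vapply(pop, eval_subset, numeric(1))
      ord <- order(fit, decreasing = TRUE)
      nextgen <- pop[ord[seq_len(elite)]]
      while (length(nextgen) < pop_size) {
        pick <- function() {
          cand <- sample.int(pop_size, tournament)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        pool <- unique(c(p1, p2))
        child <- if (length(pool) >= subset_size) sort(sample(pool, subset_size)) else p1
        if (stats::runif(1) < p_mut) {
          out_feat <- sample(seq_along(child), 1)
          repl <- sample(setdiff(seq_len(m), child), 1)
          child <- sort(c(child[-out_feat], repl))
        }
        nextgen[[length(nextgen) + 1]] <- child
      }
      pop <- nextgen
    }
    vapply(pop, eval_subset, numeric(1))   # ensure final population evaluated
  })
  keys <- ls(fitness_cache)
  if (!length(keys)) return(data.frame())
  accs <- vapply(keys, function(k) fitness_cache[[k]], numeric(1))
  keep <- accs >= min_accuracy
  keys <- keys[keep]; accs <- accs[keep]
  if (!length(keys)) {
    out <- data.frame(matrix(character(0), 0, subset_size))
    names(out) <- paste0("feature_", seq_len(subset_size))
    out$accuracy <- numeric(0)
    return(out)
  }
  ord <- order(accs, decreasing = TRUE)
  # cache keys store the sorted candidate indices joined by "|"
  mat <- do.call(rbind, lapply(keys[ord], function(k)
    candidate_features[as.integer(strsplit(k, "|", fixed = TRUE)[[1]])]))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- paste0("feature_", seq_len(subset_size))
  out$accuracy <- accs[ord]
  rownames(out) <- NULL
  out
}

#' 95% confidence ellipsoids of groups in a 3-feature morphospace
#'
#' Per group: the mean vector, covariance matrix and the chi-square scaling
#' radius sqrt(qchisq(conf, 3)) describing the confidence ellipsoid used to
#' visualize group separation in the 3D morphospace.
#'
#' @param table feature data.frame
#' @param features exactly 3 feature names
#' @param confidence coverage level (default 0.95)
#' @param groups label column name or label vector
#' @return list of per-group ellipsoids: list(group, center, covariance,
#'   radius, n); groups with n < 4 are skipped with a warning
#' @export
morphospace_ellipsoids <- function(table, features, confidence = 0.95,
                                   groups = "group") {
  stopifnot(length(features) == 3)
  gl <- factor(if (length(groups) == 1 && is.character(groups)) table[[groups]] else groups)
  X <- as.matrix(table[, features, drop = FALSE])
  out <- list()
  for (g in levels(gl)) {
    Xi <- X[gl == g & stats::complete.cases(X), , drop = FALSE]
    if (nrow(Xi) < 4) { warning("group skipped (n < 4): ", g); next }
    out[[g]] <- list(group = g,
                     center = colMeans(Xi),
                     covariance = stats::cov(Xi),
                     radius = sqrt(stats::qchisq(confidence, df = 3)),
                     confidence = confidence,
                     n = nrow(Xi))
  }
  out
}
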
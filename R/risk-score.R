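#' Weighted genetic risk score model
#'
#' A set of weighted terms: SNP main effects (log odds ratio per counted
#' allele) and optional dosage-product interaction terms. Every
#' interaction's constituent SNPs must also appear as main effects
#' (model hierarchy).
#'
#' @param terms `data.frame` with columns `snp_a`, `snp_b` (`NA` for main
#'   effects) and `beta` (finite log odds).
#' @return A `risk_score_model`.
#' @export
risk_score_model <- function(terms) {
  stopifnot(all(c("snp_a", "snp_b", "beta") %in% names(terms)),
            all(is.finite(terms$beta)))
  mains <- terms$snp_a[is.na(terms$snp_b)]
  prs <- terms[!is.na(terms$snp_b), ]
  orphan <- setdiff(unique(c(prs$snp_a, prs$snp_b)), mains)
  if (length(orphan))
    stop("interaction term lacks main effect for: ",
         paste(orphan, collapse = ", "))
  terms$term <- ifelse(is.na(terms$snp_b), terms$snp_a,
                       paste0(terms$snp_a, ":", terms$snp_b))
  structure(
    list(terms = terms[, c("term", "snp_a", "snp_b", "beta")],
         snp_ids = unique(c(terms$snp_a, terms$snp_b[!is.na(terms$snp_b)]))),
    class = "risk_score_model"
  )
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat(sprintf("risk_score_model: %d terms over %d SNPs\n",
              nrow(x$terms), length(x$snp_ids)))
  tab <- x$terms
  tab$or <- exp(tab$beta)
  print(tab[, c("term", "beta", "or")], digits = 4)
  invisible(x)
}

#' Serialise / read a risk score model as a plain-text table
#' @param model a [risk_score_model()].
#' @param path output TSV path with columns `term, beta`.
#' @return `path` (write) or a [risk_score_model()] (read).
#' @export
write_risk_score_model <- function(model, path) {
  utils::write.table(model$terms[, c("term", "beta")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_score_model
#' @export
read_risk_score_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parts <- strsplit(tab$term, ":", fixed = TRUE)
  risk_score_model(data.frame(
    snp_a = vapply(parts, `[`, "", 1),
    snp_b = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    beta = tab$beta, stringsAsFactors = FALSE
  ))
}

# design columns for a candidate term on a dosage matrix
term_column <- function(G, snp_a, snp_b) {
  if (is.na(snp_b)) G[, snp_a] else G[, snp_a] * G[, snp_b]
}

#' Bidirectional BIC stepwise selection of a predictive model
#'
#' Greedy bidirectional search over SNP main effects and dosage-product
#' pair terms minimising `BIC = -2 logLik + p log(n)`. Cohort indicator
#' covariates are forced into every model; pair terms are admissible only
#' while both main effects are present, and a main effect cannot leave
#' while a pair term depends on it (hierarchy). Individuals missing any
#' candidate genotype are excluded once, so every step compares
#' likelihoods on the same data.
#'
#' @param data a [genotype_dataset()].
#' @param main_candidates SNP ids offered as main effects.
#' @param pair_candidates list of `c(snp_a, snp_b)` pairs offered as
#'   interactions; default: all pairs of `main_candidates`.
#' @param cohort_covariate force cohort indicators (default `TRUE`).
#' @return A [risk_score_model()] carrying the fitted coefficients of the
#'   selected terms; the selection trace (step, action, term, BIC) is in
#'   `attr(, "trace")` and the final `logistic_fit`-style glm in
#'   `attr(, "fit")`.
#' @export
stepwise_bic <- function(data, main_candidates, pair_candidates = NULL,
                         cohort_covariate = TRUE) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(pair_candidates))
    pair_candidates <- utils::combn(main_candidates, 2, simplify = FALSE)
  G <- dosages(data, main_candidates)
  keep <- stats::complete.cases(G)
  G <- G[keep, , drop = FALSE]
  y <- as.integer(data$individuals$phenotype == "case")[keep]
  n <- length(y)
  cohort <- factor(data$individuals$cohort[keep])
  Xbase <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (isTRUE(cohort_covariate) && nlevels(cohort) > 1) {
    Xbase <- cbind(Xbase, stats::model.matrix(~cohort)[, -1, drop = FALSE])
  }
  cand <- data.frame(
    snp_a = c(main_candidates, vapply(pair_candidates, `[`, "", 1)),
    snp_b = c(rep(NA_character_, length(main_candidates)),
              vapply(pair_candidates, `[`, "", 2)),
    stringsAsFactors = FALSE
  )
  cand$term <- ifelse(is.na(cand$snp_b), cand$snp_a,
                      paste0(cand$snp_a, ":", cand$snp_b))
  cols <- vapply(seq_len(nrow(cand)),
                 function(i) term_column(G, cand$snp_a[i], cand$snp_b[i]),
                 numeric(n))
  colnames(cols) <- cand$term

  bic_of <- function(in_set) {
    X <- cbind(Xbase, cols[, in_set, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-10, maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(list(bic = Inf, fit = NULL))
    ll <- -fit$deviance / 2
    list(bic = -2 * ll + ncol(X) * log(n), fit = fit)
  }

  in_set <- character()
  cur <- bic_of(in_set)
  trace <- data.frame(step = 0L, action = "start", term = "",
                      bic = cur$bic, stringsAsFactors = FALSE)
  is_pair <- !is.na(cand$snp_b)
  repeat {
    moves <- list()
    mains_in <- cand$snp_a[cand$term %in% in_set & !is_pair]
    for (i in seq_len(nrow(cand))) {
      tm <- cand$term[i]
      if (!tm %in% in_set) {
        if (is_pair[i] && !(cand$snp_a[i] %in% mains_in &&
                            cand$snp_b[i] %in% mains_in)) next
        moves[[length(moves) + 1L]] <- list(action = "add", term = tm,
                                            set = c(in_set, tm))
      } else {
        if (!is_pair[i]) {
          dep <- is_pair & (cand$snp_a == cand$snp_a[i] |
                              cand$snp_b == cand$snp_a[i]) &
            cand$term %in% in_set
          if (any(dep)) next
        }
        moves[[length(moves) + 1L]] <- list(action = "drop", term = tm,
                                            set = setdiff(in_set, tm))
      }
    }
    if (!length(moves)) break
    bics <- vapply(moves, function(m) bic_of(m$set)$bic, numeric(1))
    best <- which.min(bics)
    if (bics[best] >= cur$bic - 1e-8) break
    in_set <- moves[[best]]$set
    cur <- bic_of(in_set)
    trace <- rbind(trace, data.frame(
      step = nrow(trace), action = moves[[best]]$action,
      term = moves[[best]]$term, bic = cur$bic, stringsAsFactors = FALSE))
  }

  sel <- cand[cand$term %in% in_set, ]
  # order: mains first, then pairs; refit coefficients come from cur$fit
  sel <- sel[order(is_pair[match(sel$term, cand$term)]), ]
  beta <- if (nrow(sel)) {
    cf <- cur$fit$coefficients
    unname(cf[match(sel$term, names(cf))])
  } else numeric()
  model <- risk_score_model(data.frame(
    snp_a = sel$snp_a, snp_b = sel$snp_b, beta = beta,
    stringsAsFactors = FALSE))
  attr(model, "trace") <- trace
  attr(model, "fit") <- cur$fit
  attr(model, "n") <- n
  model
}

#' Compute raw and standardised risk scores
#'
#' Raw score = sum of term betas times counted-allele dosages (dosage
#' products for interaction terms). Individuals missing any required
#' genotype are excluded, not imputed. Standardised scores are a z
#' transform over the scored individuals (or over scored controls only).
#'
#' @param model a [risk_score_model()].
#' @param data a [genotype_dataset()].
#' @param standardize `"all"` (default) or `"controls"`: the reference
#'   population for the z transform.
#' @return A `score_set` data frame: `individual_id`, `cohort`,
#'   `ethnicity`, `phenotype`, `raw`, `z`.
#' @export
compute_scores <- function(model, data, standardize = c("all", "controls")) {
  stopifnot(inherits(model, "risk_score_model"),
            inherits(data, "genotype_dataset"))
  standardize <- match.arg(standardize)
  absent <- setdiff(model$snp_ids, data$snps$snp_id)
  if (length(absent))
    stop("model SNP(s) absent from dataset: ", paste(absent, collapse = ", "))
  G <- dosages(data, model$snp_ids)
  keep <- stats::complete.cases(G)
  G <- G[keep, , drop = FALSE]
  raw <- numeric(nrow(G))
  for (i in seq_len(nrow(model$terms))) {
    raw <- raw + model$terms$beta[i] *
      term_column(G, model$terms$snp_a[i], model$terms$snp_b[i])
  }
  out <- cbind(data$individuals[keep, ], raw = raw)
  ref <- if (standardize == "controls") out$phenotype == "control" else TRUE
  mu <- mean(out$raw[ref]); sd_ <- stats::sd(out$raw[ref])
  if (sd_ == 0) stop("degenerate scores: zero variance in reference set")
  out$z <- (out$raw - mu) / sd_
  rownames(out) <- NULL
  structure(out, class = c("score_set", "data.frame"),
            standardize = standardize, n_excluded = sum(!keep))
}

#' Discriminative performance of a risk score
#'
#' Logistic regression of case status on the standardised score gives the
#' odds ratio per standard deviation with its Wald test; explained
#' variance is Nagelkerke's pseudo R-squared and discrimination the
#' C-statistic (area under the ROC curve, computed by the rank /
#' Mann-Whitney formulation with tie correction).
#'
#' @param scores a `score_set` from [compute_scores()].
#' @return `list(r2_nagelkerke, c_statistic, or_per_sd, ci, p, n)`.
#' @export
score_performance <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  y <- as.integer(scores$phenotype == "case")
  if (length(unique(y)) < 2) stop("both cases and controls are required")
  if (stats::sd(scores$z) == 0) stop("constant score")
  fit <- stats::glm(y ~ z, family = stats::binomial(), data = scores)
  cf <- summary(fit)$coefficients
  n <- length(y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- -fit$null.deviance / 2
  r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  r <- rank(scores$z)
  n1 <- sum(y); n0 <- n - n1
  cstat <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(r2_nagelkerke = r2, c_statistic = cstat,
       or_per_sd = exp(cf["z", 1]),
       ci = exp(cf["z", 1] + c(-1.96, 1.96) * cf["z", 2]),
       p = cf["z", 4], n = n)
}

#' Protective-allele count distributions and group comparisons
#'
#' Counts protective alleles per individual (a locus contributes its
#' counted-allele dosage when the model beta is negative, otherwise
#' `2 - dosage`), tabulates the distribution per group, and compares
#' groups pairwise with a chi-square test after merging distribution
#' tails inward until every expected cell count exceeds `min_expected`.
#'
#' @param data a [genotype_dataset()].
#' @param model a [risk_score_model()] providing the scored loci and
#'   their orientation (main-effect terms only).
#' @param group grouping column of the individual table (default
#'   `"ethnicity"`).
#' @param min_expected smallest tolerated expected cell count (default 5).
#' @return `list(counts, distributions, p_values)`: per-individual
#'   counts, per-group tabulation over 0..2*loci, and the pairwise
#'   p-value matrix.
#' @export
allele_count_distribution <- function(data, model, group = "ethnicity",
                                      min_expected = 5) {
  mains <- model$terms[is.na(model$terms$snp_b), ]
  G <- dosages(data, mains$snp_a)
  keep <- stats::complete.cases(G)
  G <- G[keep, , drop = FALSE]
  protective <- ifelse(rep(mains$beta < 0, each = nrow(G)), G, 2L - G)
  dim(protective) <- dim(G)
  counts <- rowSums(protective)
  ids <- data$individuals$individual_id[keep]
  grp <- data$individuals[[group]][keep]
  if (anyNA(grp)) {
    ok <- !is.na(grp)
    counts <- counts[ok]; grp <- grp[ok]; ids <- ids[ok]
  }
  max_count <- 2L * nrow(mains)
  levs <- unique(grp)
  dist <- t(vapply(levs, function(g)
    tabulate(counts[grp == g] + 1L, max_count + 1L), integer(max_count + 1L)))
  dimnames(dist) <- list(levs, as.character(0:max_count))
  pmat <- matrix(NA_real_, length(levs), length(levs),
                 dimnames = list(levs, levs))
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    pmat[i, j] <- pmat[j, i] <-
      binned_chisq(dist[i, ], dist[j, ], min_expected)$p
  }
  list(counts = data.frame(individual_id = ids, group = grp, count = counts),
       distributions = dist, p_values = pmat)
}

#' Chi-square comparison of two binned count distributions
#'
#' Homogeneity test of two count vectors over ordered bins, merging tail
#' bins inward until every expected cell count exceeds `min_expected`.
#'
#' @param x,y count vectors over the same ordered bins.
#' @param min_expected smallest tolerated expected count (default 5).
#' @return `list(statistic, df, p, bins)`.
#' @export
binned_chisq <- function(x, y, min_expected = 5) {
  tab <- rbind(x, y)
  repeat {
    if (ncol(tab) <= 2) break
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- apply(expd, 2, min) <= min_expected
    if (!any(bad)) break
    j <- if (bad[1]) 1L else if (bad[ncol(tab)]) ncol(tab) else which(bad)[1]
    if (j == ncol(tab)) {
      tab[, j - 1L] <- tab[, j - 1L] + tab[, j]
    } else {
      tab[, j + 1L] <- tab[, j + 1L] + tab[, j]
    }
    tab <- tab[, -j, drop = FALSE]
  }
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), bins = ncol(tab))
}
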
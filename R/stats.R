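#' Balanced factorial analysis of variance
#'
#' Classical fixed-effects ANOVA with all interactions for the treatment
#' factors of the experiment (water level, potassium level, growth stage, or
#' any subset — the maturation-stage two-way analysis is the same machinery
#' with the stage factor dropped). The design is required to be balanced:
#' with equal cell counts the sequential and marginal sums of squares
#' coincide, so the decomposition is unambiguous.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the response column (string).
#' @param factors Character vector of factor column names (1 to 3 of them).
#' @return An object of class `factorial_anova` wrapping the [stats::aov()]
#'   fit; use [generics::tidy()] for the per-term table and
#'   [generics::glance()] for fit summaries.
#' @examples
#' synth <- generate_dataset(seed = 1)
#' obs <- dplyr::mutate(synth$observations,
#'                      stage = ifelse(daa <= 57, "II", "III"))
#' fit <- factorial_anova(obs, "ssc", c("water", "potassium"))
#' generics::tidy(fit)
#' @export
factorial_anova <- function(data, response, factors) {
  stopifnot(is.character(response), length(response) == 1,
            response %in% names(data),
            length(factors) >= 1, length(factors) <= 3,
            all(factors %in% names(data)))
  df <- as.data.frame(data)[, c(response, factors)]
  for (f in factors) df[[f]] <- factor(df[[f]])
  cells <- table(df[factors])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    labs <- apply(empty, 1, function(idx)
      paste(mapply(function(d, i) dimnames(cells)[[d]][i], seq_along(idx), idx),
            collapse = ":"))
    rlang::abort(paste0("Empty design cell(s): ", paste(labs, collapse = ", ")))
  }
  if (length(unique(as.vector(cells))) != 1) {
    rlang::abort(paste0(
      "Unbalanced design (cell counts range ", min(cells), "-", max(cells),
      "); subset to a balanced design before fitting."))
  }
  if (any(cells < 2)) rlang::abort("ANOVA needs at least 2 replicates per cell.")
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = df)
  structure(list(fit = fit, response = response, factors = factors,
                 n_per_cell = unique(as.vector(cells)), data = df),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("Balanced factorial ANOVA of %s by %s (%d per cell)\n",
              x$response, paste(x$factors, collapse = " x "), x$n_per_cell))
  print(tidy.factorial_anova(x))
  invisible(x)
}

#' @rdname factorial_anova
#' @param x A `factorial_anova` object.
#' @param ... Unused.
#' @export
tidy.factorial_anova <- function(x, ...) {
  tab <- summary(x$fit)[[1]]
  out <- tibble::tibble(term = trimws(rownames(tab)),
                        df = tab[["Df"]],
                        sumsq = tab[["Sum Sq"]],
                        meansq = tab[["Mean Sq"]],
                        statistic = tab[["F value"]],
                        p.value = tab[["Pr(>F)"]])
  # a term explaining exactly no variance has F = 0 by convention, even in
  # the degenerate all-constant case where the residual MS is also 0
  tot <- sum(out$sumsq)
  novar <- out$term != "Residuals" &
    out$sumsq <= 1e-10 * max(tot, .Machine$double.eps)
  out$statistic[novar] <- 0
  out$p.value[novar] <- 1
  out
}

#' @rdname factorial_anova
#' @export
glance.factorial_anova <- function(x, ...) {
  td <- tidy.factorial_anova(x)
  resid_row <- td[td$term == "Residuals", ]
  tibble::tibble(nobs = nrow(x$data),
                 df.residual = resid_row$df,
                 sigma = sqrt(resid_row$meansq),
                 r.squared = 1 - resid_row$sumsq / sum(td$sumsq))
}

# Maximal cliques of the non-significance graph (Bron-Kerbosch, tiny level
# counts), used to assemble the compact letter display.
.max_cliques <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1]] <<- R
      return()
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

#' Fisher's LSD compact letter display
#'
#' All-pairwise comparisons of level means by the least significant
#' difference at level `alpha`, using the residual mean square and degrees
#' of freedom of an enclosing ANOVA, summarised as shared letters: levels
#' sharing a letter do not differ at the threshold; levels sharing none do.
#' No family-wise correction is applied, as the LSD procedure prescribes.
#' Letters follow descending means ("a" marks the largest).
#'
#' @param means Named numeric vector of level means.
#' @param n Observations per level (scalar, or named vector parallel to
#'   `means`).
#' @param ms_error Residual mean square of the enclosing model.
#' @param df_error Residual degrees of freedom (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `lsd_grouping` with `level`, `mean`, `n`,
#'   `letters`, ordered by descending mean; for equal `n` the common LSD
#'   threshold is attached as attribute `lsd`.
#' @examples
#' lsd_letters(c(CK = 97.9, T1 = 76.7, T2 = 71.2, T3 = 74.9),
#'             n = 36, ms_error = 263, df_error = 280)
#' @export
lsd_letters <- function(means, n, ms_error, df_error, alpha = 0.05) {
  stopifnot(!is.null(names(means)), df_error >= 1, ms_error >= 0,
            alpha > 0, alpha < 1)
  k <- length(means)
  if (length(n) == 1) n <- stats::setNames(rep(n, k), names(means))
  n <- n[names(means)]
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; n <- n[ord]
  tcrit <- stats::qt(1 - alpha / 2, df_error)
  lsd_mat <- outer(seq_len(k), seq_len(k), function(i, j)
    tcrit * sqrt(ms_error * (1 / n[i] + 1 / n[j])))
  diffm <- abs(outer(means, means, "-"))
  nonsig <- diffm <= lsd_mat
  diag(nonsig) <- TRUE
  cliques <- .max_cliques(nonsig)
  # letter per clique, ordered by the largest mean it contains
  cliques <- cliques[order(vapply(cliques, min, 1L))]
  lett <- vapply(seq_len(k), function(i) {
    in_cl <- vapply(cliques, function(cl) i %in% cl, logical(1))
    paste(letters[which(in_cl)], collapse = "")
  }, character(1))
  out <- tibble::tibble(level = names(means), mean = unname(means),
                        n = unname(n), letters = lett)
  if (length(unique(n)) == 1) {
    attr(out, "lsd") <- tcrit * sqrt(2 * ms_error / n[1])
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("lsd_grouping", class(out))
  out
}

#' LSD letters for one factor of a fitted factorial ANOVA
#'
#' Convenience wrapper: computes the factor-level means and pulls the
#' residual mean square and degrees of freedom from a [factorial_anova()]
#' fit, then calls [lsd_letters()].
#'
#' @param fit A `factorial_anova` object.
#' @param factor_name One of the fitted factors.
#' @param alpha Significance level.
#' @return An `lsd_grouping` tibble.
#' @export
lsd_groups <- function(fit, factor_name, alpha = 0.05) {
  stopifnot(inherits(fit, "factorial_anova"), factor_name %in% fit$factors)
  df <- fit$data
  means <- tapply(df[[fit$response]], df[[factor_name]], mean)
  ns <- tapply(df[[fit$response]], df[[factor_name]], length)
  td <- tidy.factorial_anova(fit)
  resid_row <- td[td$term == "Residuals", ]
  lsd_letters(stats::setNames(as.numeric(means), names(means)),
              stats::setNames(as.numeric(ns), names(ns)),
              resid_row$meansq, resid_row$df, alpha)
}

#' Kruskal-Wallis rank test across treatment groups
#'
#' Thin tidy wrapper around [stats::kruskal.test()] (rank-based H statistic
#' with tie correction, chi-square reference on k - 1 degrees of freedom).
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param group Grouping column name.
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `method`.
#' @export
kruskal_wallis <- function(data, response, group) {
  stopifnot(response %in% names(data), group %in% names(data))
  g <- factor(data[[group]])
  y <- data[[response]]
  if (length(unique(y)) == 1) {
    # all observations tied: no rank variation at all, H is 0 by convention
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1, p.value = 1,
                          method = "Kruskal-Wallis rank sum test"))
  }
  kt <- stats::kruskal.test(y, g)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p.value = kt$p.value,
                 method = "Kruskal-Wallis rank sum test")
}
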
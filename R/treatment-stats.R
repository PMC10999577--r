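#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition via [stats::lm()]/[stats::anova()].
#' The degenerate case of zero variance everywhere and equal means returns
#' F = 0, p = 1 by convention rather than NaN.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @return list: f_stat, p_value, mse (pooled error mean square), df_error.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  fit <- stats::lm(values ~ groups)
  # noise-free fixtures have zero residual variance; anova.lm warns about
  # the perfect fit but the F = Inf / p = 0 reading is the intended one
  an <- suppressWarnings(stats::anova(fit))
  mse <- an[["Mean Sq"]][2]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(f)) {  # zero within- and between-group variance
    if (an[["Mean Sq"]][1] == 0) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  }
  list(f_stat = f, p_value = p, mse = mse, df_error = an[["Df"]][2])
}

#' Pairwise Fisher's LSD significance matrix
#'
#' For each pair (i, j): significant iff |mean_i - mean_j| >
#' t(1 - alpha/2, df_error) * sqrt(MSE (1/n_i + 1/n_j)), with the pooled
#' error mean square from the one-way ANOVA. Unprotected by default;
#' `protected = TRUE` declares no pair significant unless the omnibus
#' ANOVA has p < alpha.
#'
#' @param values,groups observations and group labels.
#' @param alpha significance level.
#' @param protected gate pairwise tests on the omnibus test.
#' @return logical matrix (TRUE = significantly different) with the ANOVA
#'   results attached as attributes `anova`, `means`, `n`.
#' @export
lsd_pairwise <- function(values, groups, alpha = 0.05, protected = FALSE) {
  groups <- factor(groups)
  an <- one_way_anova(values, groups)
  means <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  k <- nlevels(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(levels(groups), levels(groups)))
  gate <- !protected || an$p_value < alpha
  if (gate && an$mse >= 0 && an$df_error > 0) {
    tcrit <- stats::qt(1 - alpha / 2, an$df_error)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      lsd <- tcrit * sqrt(an$mse * (1 / n[i] + 1 / n[j]))
      s <- abs(means[i] - means[j]) > lsd
      sig[i, j] <- sig[j, i] <- s
    }
  }
  attr(sig, "anova") <- an
  attr(sig, "means") <- means
  attr(sig, "n") <- n
  sig
}

# insert-and-absorb compact letter display from a significance matrix,
# over groups ordered by descending mean; ties keep stable input order
.cld_insert_absorb <- function(sig, means) {
  k <- length(means)
  ord <- order(-means, seq_len(k))           # descending mean, stable
  # columns of 'mem': letter classes; mem[g, l] TRUE = group g carries letter l
  mem <- matrix(TRUE, nrow = k, ncol = 1)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    i <- ord[a]; j <- ord[b]
    if (!sig[i, j]) next
    shared <- which(mem[i, ] & mem[j, ])
    for (l in shared) {
      # duplicate the offending column, strip i from one copy, j from the other
      newcol <- mem[, l]
      newcol[i] <- FALSE
      mem[j, l] <- FALSE
      mem <- cbind(mem, newcol)
    }
    # absorb columns whose membership is a subset of another column's
    keep <- rep(TRUE, ncol(mem))
    for (l in seq_len(ncol(mem))) for (m in seq_len(ncol(mem))) {
      if (l != m && keep[l] && keep[m] && all(mem[, l] <= mem[, m]) &&
          any(mem[, l] != mem[, m])) keep[l] <- FALSE
    }
    mem <- mem[, keep, drop = FALSE]
    mem <- mem[, !duplicated(t(mem)), drop = FALSE]
  }
  # order letter columns by the first (highest-mean) group they contain
  first <- apply(mem[ord, , drop = FALSE], 2, function(col) which(col)[1])
  mem <- mem[, order(first), drop = FALSE]
  vapply(seq_len(k), function(g) {
    paste(letters[which(mem[g, ])], collapse = "")
  }, character(1))
}

#' Compact letter display from Fisher's LSD
#'
#' Groups are sorted by descending mean and letters a, b, c, ... assigned
#' by insert-and-absorb so that two groups share a letter if and only if
#' their pairwise LSD test is not significant.
#'
#' @inheritParams lsd_pairwise
#' @return named character vector of letter strings, in the factor's
#'   level order.
#' @export
lsd_letters <- function(values, groups, alpha = 0.05, protected = FALSE) {
  sig <- lsd_pairwise(values, groups, alpha, protected)
  means <- attr(sig, "means")
  out <- .cld_insert_absorb(sig, means)
  names(out) <- rownames(sig)
  out
}

#' Mean and sample standard deviation
#'
#' @param x numeric observations.
#' @return list(mean, sd, flag); a single observation reports sd 0 with
#'   flag "single_observation".
#' @export
summarize_mean_sd <- function(x) {
  if (length(x) == 1) {
    return(list(mean = x, sd = 0, flag = "single_observation"))
  }
  list(mean = mean(x), sd = stats::sd(x), flag = "")
}

#' Treatment comparison table (mean +/- sd with LSD letters)
#'
#' Runs the one-way ANOVA and LSD letter assignment for each response
#' variable across treatments, producing rows in the mean +/- sd + letter
#' layout conventional for agronomic tables.
#'
#' @param data data.frame with a `treatment_id` column and numeric
#'   response columns.
#' @param variables response column names; default all numeric columns
#'   except identifiers.
#' @param alpha significance level.
#' @param protected see [lsd_pairwise()].
#' @return data.frame: variable, treatment_id, mean, sd, n, letters,
#'   f_stat, p_value; class `group_comparison`.
#' @export
treatment_comparison <- function(data, variables = NULL, alpha = 0.05,
                                 protected = FALSE) {
  if (is.null(variables)) {
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         c("replicate", "day"))
  }
  tr <- factor(data$treatment_id, levels = unique(data$treatment_id))
  rows <- lapply(variables, function(v) {
    ok <- is.finite(data[[v]])
    x <- data[[v]][ok]; g <- droplevels(tr[ok])
    an <- one_way_anova(x, g)
    let <- lsd_letters(x, g, alpha, protected)
    m <- tapply(x, g, mean); s <- tapply(x, g, stats::sd)
    data.frame(variable = v, treatment_id = levels(g), mean = as.numeric(m),
               sd = as.numeric(s), n = as.numeric(table(g)),
               letters = let[levels(g)], f_stat = an$f_stat,
               p_value = an$p_value, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, digits = 2, ...) {
  for (v in unique(x$variable)) {
    d <- x[x$variable == v, ]
    cat(sprintf("%s (F = %.3g, p = %.3g)\n", v, d$f_stat[1], d$p_value[1]))
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %-10s %s %s\n", d$treatment_id[i],
                  format(round(d$mean[i], digits), nsmall = digits),
                  paste0("± ", format(round(d$sd[i], digits),
                                           nsmall = digits), d$letters[i])))
    }
  }
  invisible(x)
}
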
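#' PCA morphospace of bead-corrected morphology
#'
#' Column-centred principal component analysis of the per-cell morphology
#' channels (no scaling: channels are already bead-corrected and share the
#' instrument's log scale). Components are ordered by decreasing variance with
#' a deterministic sign convention: within each component, the
#' largest-magnitude loading is made positive.
#'
#' @param data A data frame of cells; metadata columns are carried through to
#'   the scores.
#' @param channels Channel columns to decompose (default the bead-corrected
#'   triplet).
#' @return An object of class `morphospace`: a list with `scores` (tibble of
#'   metadata plus `PC1..PCk`), `loadings` (channels x components),
#'   `sdev`, and `prop_var` (proportion of variance per component).
#' @examples
#' x <- data.frame(fsc_c = rnorm(50), ssc_c = rnorm(50), red_b_c = rnorm(50))
#' pca_morphospace(x)$prop_var
#' @export
pca_morphospace <- function(data, channels = corrected_channels()) {
  assert_columns(data, channels)
  if (nrow(data) < 3) stop("need at least 3 rows for a PCA", call. = FALSE)
  Y <- as.matrix(data[channels])
  p <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(p$rotation))) {
    j <- which.max(abs(p$rotation[, k]))
    if (p$rotation[j, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  scores <- dplyr::bind_cols(
    data[setdiff(names(data), channels)],
    tibble::as_tibble(p$x)
  )
  structure(list(scores = scores, loadings = p$rotation, sdev = p$sdev,
                 prop_var = p$sdev^2 / sum(p$sdev^2), center = p$center,
                 channels = channels),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat("PCA morphospace:", nrow(x$scores), "cells,",
      length(x$sdev), "components\n")
  cat("proportion of variance:",
      paste(sprintf("%.3f", x$prop_var), collapse = " "), "\n")
  invisible(x)
}

#' Condition centroids in morphospace
#'
#' Mean scores per condition (a given salinity, day and line), optionally
#' averaged over lines per autocorrelation treatment with standard errors
#' across lines. The treatment-level table is what a day-ordered morphospace
#' trajectory plot is built from.
#'
#' @param scores A tibble of cell scores with columns `line_id`, `salinity_M`,
#'   `day` plus the score axes (e.g. the `scores` element of a
#'   [pca_morphospace()]).
#' @param design Optional design tibble (`line_id`, `rho_bar`, `regime`); when
#'   supplied, line centroids are averaged per treatment (`rho_bar`, with
#'   constant-regime lines as their own group) and per salinity and day.
#' @param axes Score columns to average (default `PC1`, `PC2`).
#' @return A tibble of line-level centroids (`design = NULL`) or
#'   treatment-level means with per-axis standard errors (`se_*`; `NA` when a
#'   treatment has a single line) and `n_lines`.
#' @export
condition_centroids <- function(scores, design = NULL, axes = c("PC1", "PC2")) {
  assert_columns(scores, c("line_id", "salinity_M", "day", axes))
  line_level <- scores |>
    dplyr::group_by(.data$line_id, .data$salinity_M, .data$day) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(axes), mean),
                     n_cells = dplyr::n(), .groups = "drop")
  if (is.null(design)) {
    return(line_level)
  }
  assert_columns(design, c("line_id", "regime"), "design")
  joined <- line_level |>
    dplyr::inner_join(design, by = "line_id") |>
    dplyr::mutate(treatment = ifelse(.data$regime == "constant", "constant",
                                     as.character(.data$rho_bar)))
  dropped <- nrow(line_level) - nrow(joined)
  if (dropped > 0) {
    warning(sprintf("%d line-condition centroid(s) without design metadata dropped",
                    dropped), call. = FALSE)
  }
  joined |>
    dplyr::group_by(.data$treatment, .data$salinity_M, .data$day) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(axes),
                    list(mean = mean,
                         se = ~ if (dplyr::n() > 1) sd(.x) / sqrt(dplyr::n()) else NA_real_),
                    .names = "{.fn}_{.col}"),
      n_lines = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("^mean_", "", .x))
}

# ---- design encoding -------------------------------------------------------

encode_variable <- function(metadata, var) {
  x <- metadata[[var]]
  if (anyNA(x)) stop(sprintf("metadata column `%s` contains NA", var), call. = FALSE)
  if (var %in% c("day", "salinity", "salinity_M", "strain") || is.character(x) ||
      is.factor(x)) {
    f <- factor(x)
    if (nlevels(f) < 2) {
      return(matrix(numeric(nrow(metadata)), ncol = 1,
                    dimnames = list(NULL, paste0(var, levels(f)[1]))))
    }
    m <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.treatment"))
    m <- m[, -1, drop = FALSE]
    colnames(m) <- paste0(var, levels(f)[-1])
    m
  } else {
    matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, var))
  }
}

interaction_columns <- function(mats) {
  out <- mats[[1]]
  for (m in mats[-1]) {
    pieces <- lapply(seq_len(ncol(out)), function(i) {
      p <- out[, i] * m
      colnames(p) <- paste(colnames(out)[i], colnames(m), sep = ":")
      p
    })
    out <- do.call(cbind, pieces)
  }
  out
}

#' Build an ordered explanatory-term list for variation partitioning
#'
#' Encodes the per-cell metadata into an ordered list of design terms: `day`
#' and `salinity` as categorical factors with treatment contrasts, growth rate
#' and predictability (rho^2) as continuous covariates, and interactions as
#' column products of the component encodings. The default term order is the
#' partitioning-table order for each regime: for lines evolved in fluctuating
#' salinity -- strain, growth rate, day, salinity, rho^2, salinity x rho^2,
#' day x salinity, day x rho^2, day x salinity x rho^2; for constant-regime
#' lines the rho^2 terms are dropped. Day 0 (pre-transfer acclimation) should
#' be excluded by the caller; with assay days 1-10 the day term then carries
#' 9 df.
#'
#' @param metadata Per-cell metadata with the columns each requested term
#'   needs (`strain`, `growth_rate`, `day`, `salinity`, `predictability`).
#' @param regime `"fluctuating"` or `"constant"`; sets the default term list.
#' @param terms Optional character vector of term names; components of an
#'   interaction are separated by `:`.
#' @return A list of class `rda_design`; each element has `name`, `mat`
#'   (encoded columns) and `df` (nominal column count).
#' @export
build_design <- function(metadata,
                         regime = c("fluctuating", "constant"),
                         terms = NULL) {
  regime <- match.arg(regime)
  if (is.null(terms)) {
    terms <- if (regime == "fluctuating") {
      c("strain", "growth_rate", "day", "salinity", "predictability",
        "salinity:predictability", "day:salinity", "day:predictability",
        "day:salinity:predictability")
    } else {
      c("strain", "growth_rate", "day", "salinity", "day:salinity")
    }
  }
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  # accept salinity_M as the salinity column name
  meta <- metadata
  if (!"salinity" %in% names(meta) && "salinity_M" %in% names(meta)) {
    meta$salinity <- meta$salinity_M
  }
  assert_columns(meta, base_vars, "metadata")
  enc <- lapply(setNames(base_vars, base_vars), function(v) encode_variable(meta, v))
  out <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    mat <- if (length(parts) == 1) enc[[parts]] else interaction_columns(enc[parts])
    list(name = tm, mat = mat, df = ncol(mat))
  })
  names(out) <- terms
  class(out) <- "rda_design"
  out
}

# ---- RDA variation partitioning -------------------------------------------

# Orthonormal basis of the columns of M not already spanned by Q (n x k).
# Returns a matrix with rank(M | Q) columns (possibly 0).
basis_increment <- function(M, Q, tol = 1e-9) {
  R <- M - if (ncol(Q)) Q %*% crossprod(Q, M) else 0
  if (max(abs(R)) < tol) return(matrix(numeric(0), nrow = nrow(M), ncol = 0))
  qr_r <- qr(R)  # LINPACK pivoted decomposition; $rank at default tolerance
  rank <- qr_r$rank
  d <- abs(diag(qr_r$qr))
  if (length(d)) rank <- min(rank, sum(d > tol * max(d)))
  if (rank == 0) return(matrix(numeric(0), nrow = nrow(M), ncol = 0))
  qr.Q(qr_r)[, seq_len(rank), drop = FALSE]
}

#' RDA variation partitioning with permutation tests
#'
#' Redundancy analysis reduces to multivariate least squares: each explanatory
#' term's contribution is the fitted sum of squares it adds to the multivariate
#' response, given all earlier terms (sequential attribution in the supplied
#' order). Each term's share of total variation is the multivariate
#' \eqn{R^2 = SS_{term}/SS_{total}}, its pseudo-F is
#' \eqn{(SS_{term}/df_{term}) / (SS_{res}/df_{res})}, and significance comes
#' from ANOVA-like permutation tests: response rows are freely permuted,
#' the full decomposition recomputed, and
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' Marginal (partial) \eqn{R^2} of each term given all others is also
#' available; sequential attribution in table order is the default.
#'
#' @param Y Numeric matrix or data frame of response channels (cells x 3).
#' @param design An [build_design()] term list (class `rda_design`).
#' @param n_perm Number of permutations (default 999; with 999 the smallest
#'   attainable p is 0.001).
#' @param seed Optional seed for the permutations.
#' @param marginal Add a `r2_marginal` column (default FALSE).
#' @param permute `"free"` (permute response rows; default) or `"residual"`
#'   (permute residuals of the reduced model preceding each term).
#' @return A tibble of class `rda_partition` with one row per term plus
#'   `Residual` and `Total` rows: columns `term`, `df`, `variance`
#'   (SS/(n-1)), `F`, `r2`, `p` (and `r2_marginal` if requested). A term whose
#'   added columns are collinear with earlier terms has its df reduced, with a
#'   warning.
#' @examples
#' md <- data.frame(salinity = rep(c(0.8, 4.0), each = 10))
#' Y <- matrix(rnorm(60), 20, 3)
#' rda_partition(Y, build_design(md, terms = "salinity"), n_perm = 99, seed = 1)
#' @export
rda_partition <- function(Y, design, n_perm = 999, seed = NULL,
                          marginal = FALSE, permute = c("free", "residual")) {
  permute <- match.arg(permute)
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (!inherits(design, "rda_design")) {
    stop("`design` must come from build_design()", call. = FALSE)
  }
  n <- nrow(Y)
  if (any(vapply(design, function(t) nrow(t$mat), 0L) != n)) {
    stop("design and response have different row counts", call. = FALSE)
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response has zero total variance", call. = FALSE)

  # sequential orthonormal increments
  Q <- matrix(numeric(0), nrow = n, ncol = 0)
  incs <- vector("list", length(design))
  dfs <- integer(length(design))
  for (k in seq_along(design)) {
    mat <- scale(design[[k]]$mat, center = TRUE, scale = FALSE)
    inc <- basis_increment(mat, Q)
    if (ncol(inc) < design[[k]]$df) {
      warning(sprintf("term `%s`: df reduced from %d to %d (collinearity)",
                      design[[k]]$name, design[[k]]$df, ncol(inc)),
              call. = FALSE)
    }
    incs[[k]] <- inc
    dfs[k] <- ncol(inc)
    Q <- cbind(Q, inc)
  }
  df_total <- sum(dfs)
  df_res <- n - 1 - df_total
  if (df_res < 1) stop("not enough residual degrees of freedom", call. = FALSE)

  term_index <- rep(seq_along(design), dfs)
  Z <- crossprod(Q, Yc)                       # (sum df) x ncol(Y)
  ss_rows <- rowSums(Z^2)
  ss_term <- vapply(seq_along(design),
                    function(k) sum(ss_rows[term_index == k]), 0)
  ss_res <- ss_tot - sum(ss_term)
  F_obs <- (ss_term / pmax(dfs, 1)) / (ss_res / df_res)
  F_obs[dfs == 0] <- NA_real_

  # permutation null
  p_val <- rep(NA_real_, length(design))
  if (n_perm > 0) {
    exceed <- integer(length(design))
    # "residual": ter Braak-style permutation of residuals under the full
    # model (fitted part kept fixed, residual rows shuffled).
    Fit <- Q %*% Z
    Res <- Yc - Fit
    run_perms <- function() {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        Yp <- if (permute == "free") Yc[idx, , drop = FALSE] else
          Fit + Res[idx, , drop = FALSE]
        Zp <- crossprod(Q, Yp)
        ssp_rows <- rowSums(Zp^2)
        ssp_term <- vapply(seq_along(design),
                           function(k) sum(ssp_rows[term_index == k]), 0)
        ssp_tot <- if (permute == "free") ss_tot else sum(Yp^2)
        ssp_res <- ssp_tot - sum(ssp_term)
        Fp <- (ssp_term / pmax(dfs, 1)) / (ssp_res / df_res)
        exceed <<- exceed + (!is.na(F_obs) & Fp >= F_obs)
      }
    }
    with_seed_or_not(seed, run_perms())
    p_val <- (1 + exceed) / (1 + n_perm)
    p_val[dfs == 0] <- NA_real_
  }

  r2 <- ss_term / ss_tot
  out <- tibble::tibble(
    term = vapply(design, `[[`, "", "name"),
    df = dfs,
    variance = ss_term / (n - 1),
    F = F_obs,
    r2 = r2,
    p = p_val
  )

  if (marginal) {
    r2m <- vapply(seq_along(design), function(k) {
      others <- do.call(cbind, lapply(design[-k], function(t) {
        scale(t$mat, center = TRUE, scale = FALSE)
      }))
      ss_others <- if (is.null(others) || ncol(others) == 0) 0 else {
        Qo <- basis_increment(others, matrix(numeric(0), n, 0))
        sum(crossprod(Qo, Yc)^2)
      }
      (sum(ss_term) - ss_others) / ss_tot
    }, 0)
    out$r2_marginal <- r2m
  }

  out <- dplyr::bind_rows(
    out,
    tibble::tibble(term = "Residual", df = df_res, variance = ss_res / (n - 1),
                   F = NA_real_, r2 = ss_res / ss_tot, p = NA_real_),
    tibble::tibble(term = "Total", df = n - 1, variance = ss_tot / (n - 1),
                   F = NA_real_, r2 = 1, p = NA_real_)
  )
  class(out) <- c("rda_partition", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n") <- n
  out
}
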
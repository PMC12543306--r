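#' Pairwise connectome similarity (Fisher-z)
#'
#' For every pair of sessions, computes the Pearson correlation between the
#' two connectomes' canonical edge vectors and Fisher-transforms it
#' (`atanh`), after clipping `|r| <= 1 - 1e-7` so that identical connectomes
#' give a large but finite z. Pairs involving a zero-variance edge vector are
#' undefined (`NA`) and excluded from all summaries.
#'
#' @param study An `"fc_study"`, or a plain list of [connectome()] objects
#'   over an identical region set.
#' @return List of class `"similarity_matrix"` with `z` and `r` (symmetric
#'   session-by-session matrices, diagonal `NA`) and `session_keys`.
#' @export
pairwise_similarity <- function(study) {
  conns <- if (inherits(study, "fc_study")) study$connectomes else study
  if (length(conns) < 2) stop("need >= 2 connectomes")
  ev <- vapply(conns, vectorize, numeric(length(vectorize(conns[[1]]))))
  keys <- names(conns) %||% sprintf("session_%03d", seq_along(conns))
  sds <- apply(ev, 2, stats::sd)
  r <- suppressWarnings(stats::cor(ev))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  z <- atanh(clip_r(r))
  diag(z) <- NA_real_
  diag(r) <- NA_real_
  dimnames(z) <- dimnames(r) <- list(keys, keys)
  structure(list(z = z, r = r, session_keys = keys),
            class = "similarity_matrix")
}

#' Label session pairs by the similarity category they inform
#'
#' Every unordered session pair is assessed against four (overlapping)
#' category definitions: *individual* (same subject, any sessions), *dataset*
#' (different subjects, same dataset), *hc_use* (different subjects, same
#' HC-use status), and *group* (any pair of different subjects). Because the
#' definitions nest, a membership flag is stored per definition, plus a
#' mutually exclusive `primary` label (precedence individual > dataset >
#' hc_use > group) suitable for bar-style displays. Pairs with a missing
#' subject/dataset/HC label are marked `excluded`.
#'
#' @param sessions Session table with columns `subject_id`, `dataset_id`,
#'   `hc_use`.
#' @return Data frame of class `"pair_categories"`: one row per unordered
#'   pair with columns `a`, `b` (session indices), `key_a`, `key_b`,
#'   membership flags `is_individual`, `is_dataset`, `is_hc_use`,
#'   `is_group`, and `primary`.
#' @export
classify_pairs <- function(sessions) {
  n <- nrow(sessions)
  if (n < 2) stop("need >= 2 sessions")
  pr <- edge_pairs(n)
  a <- pr[, 1]; b <- pr[, 2]
  keys <- paste(sessions$subject_id, sessions$session_id, sep = "_")
  ok <- !(is.na(sessions$subject_id[a]) | is.na(sessions$subject_id[b]) |
            is.na(sessions$dataset_id[a]) | is.na(sessions$dataset_id[b]) |
            is.na(sessions$hc_use[a]) | is.na(sessions$hc_use[b]))
  same_subj <- sessions$subject_id[a] == sessions$subject_id[b]
  same_ds <- sessions$dataset_id[a] == sessions$dataset_id[b]
  same_hc <- sessions$hc_use[a] == sessions$hc_use[b]

  out <- data.frame(
    a = a, b = b, key_a = keys[a], key_b = keys[b],
    is_individual = ok & same_subj,
    is_dataset = ok & !same_subj & same_ds,
    is_hc_use = ok & !same_subj & same_hc,
    is_group = ok & !same_subj
  )
  out$primary <- ifelse(!ok, "excluded",
                 ifelse(out$is_individual, "individual",
                 ifelse(out$is_dataset, "dataset",
                 ifelse(out$is_hc_use, "hc_use", "group"))))
  if (any(!ok)) {
    message(sum(!ok), " pair(s) excluded for missing labels")
  }
  class(out) <- c("pair_categories", "data.frame")
  out
}

#' Summarize similarity by category and contrast categories
#'
#' Computes, per category, the number of pairs and the mean and SD of the
#' Fisher-z similarity, then contrasts every pair of categories with a Welch
#' two-sample t-test (two-sided), flagged significant at `alpha`. By default
#' each category is taken over *all* pairs meeting its own definition
#' (membership scheme; categories overlap); `scheme = "exclusive"` instead
#' uses the mutually exclusive primary labels. Pairwise z values share
#' sessions and are therefore not independent observations; the t-tests
#' ignore this, which is the convention this analysis follows.
#'
#' @param sim A `"similarity_matrix"` from [pairwise_similarity()].
#' @param pairs A `"pair_categories"` from [classify_pairs()].
#' @param scheme `"membership"` (default) or `"exclusive"`.
#' @param alpha Significance threshold for the contrasts (default 0.01).
#' @return List of class `"category_similarity"` with `summary` (category,
#'   n_pairs, mean_z, sd_z), `contrasts` (category_a, category_b, t, df,
#'   p_value, significant), `scheme`, and `alpha`.
#' @export
category_summary <- function(sim, pairs, scheme = c("membership", "exclusive"),
                             alpha = 0.01) {
  scheme <- match.arg(scheme)
  z <- sim$z[cbind(pairs$a, pairs$b)]
  cats <- c("group", "dataset", "hc_use", "individual")
  values <- lapply(stats::setNames(cats, cats), function(cc) {
    sel <- if (scheme == "membership") {
      pairs[[paste0("is_", cc)]]
    } else {
      pairs$primary == cc
    }
    z[sel & !is.na(z)]
  })
  values <- Filter(length, values)

  summary <- data.frame(
    category = names(values),
    n_pairs = vapply(values, length, integer(1)),
    mean_z = vapply(values, mean, numeric(1)),
    sd_z = vapply(values, stats::sd, numeric(1)),
    row.names = NULL
  )

  empty_contrasts <- data.frame(category_a = character(),
                                category_b = character(), t = numeric(),
                                df = numeric(), p_value = numeric(),
                                significant = logical())
  if (length(values) < 2) {
    return(structure(list(summary = summary, contrasts = empty_contrasts,
                          scheme = scheme, alpha = alpha),
                     class = "category_similarity"))
  }
  combos <- utils::combn(names(values), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    ca <- combos[1, k]; cb <- combos[2, k]
    if (length(values[[ca]]) < 2 || length(values[[cb]]) < 2) {
      return(data.frame(category_a = ca, category_b = cb, t = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    if (stats::sd(values[[ca]]) == 0 && stats::sd(values[[cb]]) == 0) {
      # degenerate case: no within-category spread
      d <- mean(values[[ca]]) - mean(values[[cb]])
      return(data.frame(category_a = ca, category_b = cb,
                        t = if (d == 0) 0 else sign(d) * Inf,
                        df = NA_real_, p_value = as.numeric(d == 0),
                        significant = d != 0))
    }
    tt <- stats::t.test(values[[ca]], values[[cb]], var.equal = FALSE)
    data.frame(category_a = ca, category_b = cb,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, significant = tt$p.value < alpha)
  }))
  structure(list(summary = summary, contrasts = contrasts,
                 scheme = scheme, alpha = alpha),
            class = "category_similarity")
}

#' @export
print.category_similarity <- function(x, ...) {
  cat("<category_similarity> scheme:", x$scheme, "\n")
  print(x$summary, row.names = FALSE)
  sig <- x$contrasts[which(x$contrasts$significant), , drop = FALSE]
  cat(nrow(sig), "contrast(s) significant at alpha <", x$alpha, "\n")
  invisible(x)
}

#' Normalized effect magnitude between two similarity categories
#'
#' The difference between two categories' mean Fisher-z similarities; used to
#' compare the relative contributions of factors (e.g. individual-specific
#' factors over and above shared group factors).
#'
#' @param z_a,z_b Mean Fisher-z similarity of the two categories.
#' @return `z_a - z_b`.
#' @examples
#' normalized_effect_magnitude(1.07, 0.59)  # 0.48
#' @export
normalized_effect_magnitude <- function(z_a, z_b) {
  stopifnot(is.finite(z_a), is.finite(z_b))
  z_a - z_b
}

#' Write similarity outputs as TSV tables
#'
#' Writes `similarity.tsv` (long pair table with r, z, and category labels),
#' `category_summary.tsv`, and `contrasts.tsv` under `dir`.
#'
#' @param sim A `"similarity_matrix"`.
#' @param pairs A `"pair_categories"`.
#' @param summary A `"category_similarity"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_similarity <- function(sim, pairs, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- data.frame(
    session_a = pairs$key_a, session_b = pairs$key_b,
    r = sim$r[cbind(pairs$a, pairs$b)],
    z = sim$z[cbind(pairs$a, pairs$b)],
    pairs[, c("is_individual", "is_dataset", "is_hc_use", "is_group",
              "primary")]
  )
  utils::write.table(long, file.path(dir, "similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(summary$summary, file.path(dir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(summary$contrasts, file.path(dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}
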
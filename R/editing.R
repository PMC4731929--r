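#' Construct an editing count table
#'
#' Per-site edited/unedited read counts across a 3-group x 3-replicate
#' design (empty vector EV plus two protein-isoform conditions).
#'
#' @param sites data.frame with `chrom`, `pos` (1-based site position, as in
#'   editing-site databases), `strand`.
#' @param e,u integer matrices (sites x libraries) of edited and unedited
#'   counts; column names must match `manifest$library`.
#' @param manifest data.frame with `library`, `group`, `replicate`; exactly
#'   3 replicates per group expected.
#' @return object of class `editing_counts`.
#' @export
editing_counts <- function(sites, e, u, manifest) {
  e <- as.matrix(e); u <- as.matrix(u)
  if (!all(c("library", "group", "replicate") %in% names(manifest))) {
    stop("malformed library manifest: need library, group, replicate")
  }
  if (!identical(sort(colnames(e)), sort(manifest$library)) ||
      !identical(sort(colnames(u)), sort(manifest$library))) {
    stop("count matrix columns must match the manifest libraries")
  }
  if (any(e < 0) || any(u < 0) || any(e != round(e)) || any(u != round(u))) {
    stop("counts must be non-negative integers")
  }
  if (nrow(sites) != nrow(e) || nrow(sites) != nrow(u)) {
    stop("sites and count matrices must have equal row counts")
  }
  site_id <- sprintf("%s:%d:%s", sites$chrom, sites$pos, sites$strand)
  rownames(e) <- rownames(u) <- site_id
  structure(list(sites = cbind(site_id = site_id, sites),
                 e = e[, manifest$library, drop = FALSE],
                 u = u[, manifest$library, drop = FALSE],
                 manifest = manifest),
            class = "editing_counts")
}

#' @export
print.editing_counts <- function(x, ...) {
  cat(sprintf("<editing_counts> %d site(s), %d libraries (%s)\n",
              nrow(x$e), ncol(x$e),
              paste(unique(x$manifest$group), collapse = "/")))
  invisible(x)
}

group_cols <- function(x, group) {
  libs <- x$manifest$library[x$manifest$group == group]
  if (length(libs) == 0) stop(sprintf("group '%s' absent from manifest", group))
  libs
}

#' Filter editing sites on evidence and coverage
#'
#' Keeps a site iff (i) at least one of the nine libraries has
#' `>= min_edited` edited reads, and (ii) every group has read coverage
#' (edited + unedited > 0) in at least one replicate.
#'
#' @param x an `editing_counts` object.
#' @param min_edited minimum edited count in some library (default 5).
#' @return the filtered `editing_counts`.
#' @export
filter_editing_sites <- function(x, min_edited = 5L) {
  stopifnot(inherits(x, "editing_counts"))
  has_evidence <- apply(x$e, 1, max) >= min_edited
  groups <- unique(x$manifest$group)
  has_cov <- rep(TRUE, nrow(x$e))
  for (g in groups) {
    cols <- group_cols(x, g)
    has_cov <- has_cov &
      apply(x$e[, cols, drop = FALSE] + x$u[, cols, drop = FALSE], 1, max) > 0
  }
  keep <- has_evidence & has_cov
  out <- x
  out$sites <- x$sites[keep, , drop = FALSE]
  out$e <- x$e[keep, , drop = FALSE]
  out$u <- x$u[keep, , drop = FALSE]
  out
}

#' Replicate-merged editing levels per site
#'
#' Reads of the group's replicates are pooled; the level is the fraction of
#' edited counts over total counts in the merged data.
#'
#' @param x an `editing_counts` object.
#' @param group group name, e.g. "EV", "SHORT", "LONG".
#' @return data.frame with `site_id`, `level` (NA where total = 0), `total`.
#' @export
merged_editing_levels <- function(x, group) {
  cols <- group_cols(x, group)
  e <- rowSums(x$e[, cols, drop = FALSE])
  tot <- e + rowSums(x$u[, cols, drop = FALSE])
  data.frame(site_id = rownames(x$e),
             level = ifelse(tot > 0, e / tot, NA_real_),
             total = tot, stringsAsFactors = FALSE, row.names = NULL)
}

#' Global comparison of editing levels between two groups
#'
#' Merged editing levels of sites with total coverage >= `min_total` in both
#' groups are compared with a paired two-tailed Wilcoxon signed-rank test
#' over the shared sites.
#'
#' @param x an `editing_counts` object.
#' @param group_a,group_b group names.
#' @param min_total per-group merged coverage gate (default 50).
#' @return list with `n_sites`, per-group mean levels and standard errors
#'   (across sites), and the Wilcoxon `p`.
#' @export
global_editing_comparison <- function(x, group_a, group_b, min_total = 50L) {
  la <- merged_editing_levels(x, group_a)
  lb <- merged_editing_levels(x, group_b)
  keep <- !is.na(la$level) & !is.na(lb$level) &
    la$total >= min_total & lb$total >= min_total
  if (sum(keep) < 2) stop("fewer than 2 shared gated sites")
  a <- la$level[keep]; b <- lb$level[keep]
  w <- wilcoxon_signed_rank(a, b, two_tailed = TRUE)
  list(n_sites = sum(keep),
       mean_a = mean(a), se_a = stats::sd(a) / sqrt(length(a)),
       mean_b = mean(b), se_b = stats::sd(b) / sqrt(length(b)),
       p = w$p)
}

#' Differential editing of one isoform condition against the control
#'
#' For each site, a two-sided Fisher exact test compares the edited/unedited
#' counts of each treatment replicate with its paired control replicate
#' (replicate k vs EV replicate k by default; `pairing = "pooled"` compares
#' each replicate against the summed EV counts). The three p-values are
#' combined with Fisher's method (6 df) and BH-corrected across all sites;
#' sites with q <= `fdr_threshold` are called differential. A replicate pair
#' with zero coverage contributes p = 1 and is flagged.
#'
#' @param x an `editing_counts` object (typically after
#'   [filter_editing_sites()]).
#' @param isoform_group treatment group name.
#' @param ev_group control group name (default "EV").
#' @param pairing "indexed" (default) or "pooled".
#' @param fdr_threshold BH q cutoff (default 0.10, inclusive).
#' @return data.frame of class `differential_editing`: `site_id`, `p_rep1..3`,
#'   `chi2`, `p_combined`, `q`, `differential`, `n_zero_coverage`.
#' @export
differential_editing <- function(x, isoform_group, ev_group = "EV",
                                 pairing = c("indexed", "pooled"),
                                 fdr_threshold = 0.10) {
  pairing <- match.arg(pairing)
  tcols <- group_cols(x, isoform_group)
  ecols <- group_cols(x, ev_group)
  tord <- order(x$manifest$replicate[match(tcols, x$manifest$library)])
  eord <- order(x$manifest$replicate[match(ecols, x$manifest$library)])
  tcols <- tcols[tord]; ecols <- ecols[eord]
  n_rep <- length(tcols)

  n_sites <- nrow(x$e)
  p_rep <- matrix(NA_real_, n_sites, n_rep)
  n_zero <- integer(n_sites)
  ev_e_pool <- rowSums(x$e[, ecols, drop = FALSE])
  ev_u_pool <- rowSums(x$u[, ecols, drop = FALSE])
  for (i in seq_len(n_sites)) {
    for (k in seq_len(n_rep)) {
      te <- x$e[i, tcols[k]]; tu <- x$u[i, tcols[k]]
      if (pairing == "indexed") {
        ee <- x$e[i, ecols[k]]; eu <- x$u[i, ecols[k]]
      } else {
        ee <- ev_e_pool[i]; eu <- ev_u_pool[i]
      }
      tab <- matrix(c(te, tu, ee, eu), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        if (te + tu == 0 || ee + eu == 0) n_zero[i] <- n_zero[i] + 1L
        p_rep[i, k] <- 1
      } else {
        p_rep[i, k] <- fisher_exact_2x2(tab)$p
      }
    }
  }
  p_floor <- pmax(p_rep, .Machine$double.xmin)  # guard log(0) underflow
  chi2 <- -2 * rowSums(log(p_floor))
  p_comb <- stats::pchisq(chi2, df = 2 * n_rep, lower.tail = FALSE)
  q <- bh_fdr(p_comb)
  out <- data.frame(site_id = rownames(x$e), stringsAsFactors = FALSE)
  for (k in seq_len(n_rep)) out[[paste0("p_rep", k)]] <- p_rep[, k]
  out$chi2 <- chi2
  out$p_combined <- p_comb
  out$q <- q
  out$differential <- q <= fdr_threshold
  out$n_zero_coverage <- n_zero
  rownames(out) <- NULL
  class(out) <- c("differential_editing", "data.frame")
  out
}

#' Classify sites as common versus isoform-specific differential editing
#'
#' COMMON when both isoforms reach q <= `q_low`; HIGH_CONF_X when one
#' isoform reaches q <= `q_low` while the other has q >= `q_high` (the
#' high-confidence isoform-specific rule); LOW_CONF_X when the other
#' isoform's q lies strictly between the cutoffs; otherwise
#' NOT_DIFFERENTIAL. Sites missing a q-value on either side are skipped and
#' tallied.
#'
#' @param calls_short,calls_long `differential_editing` results for the two
#'   isoform conditions.
#' @param q_low,q_high confidence cutoffs (defaults 0.10 and 0.90).
#' @return data.frame with `site_id`, `q_short`, `q_long`,
#'   `classification`; attribute `n_skipped`.
#' @export
classify_specificity <- function(calls_short, calls_long,
                                 q_low = 0.10, q_high = 0.90) {
  m <- merge(calls_short[, c("site_id", "q")],
             calls_long[, c("site_id", "q")],
             by = "site_id", suffixes = c("_short", "_long"), all = TRUE)
  miss <- is.na(m$q_short) | is.na(m$q_long)
  n_skipped <- sum(miss)
  m <- m[!miss, , drop = FALSE]
  cls <- function(qs, ql) {
    if (qs <= q_low && ql <= q_low) return("COMMON")
    if (qs <= q_low) {
      if (ql >= q_high) return("HIGH_CONF_SHORT")
      return("LOW_CONF_SHORT")
    }
    if (ql <= q_low) {
      if (qs >= q_high) return("HIGH_CONF_LONG")
      return("LOW_CONF_LONG")
    }
    "NOT_DIFFERENTIAL"
  }
  m$classification <- mapply(cls, m$q_short, m$q_long)
  rownames(m) <- NULL
  attr(m, "n_skipped") <- n_skipped
  m
}
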
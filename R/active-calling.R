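# Active-translation calling for candidate uORFs from P-site profiles.
#
# The score combines the codon-stepping signature of translating ribosomes
# (3-nt periodicity) with the uniformity of the read distribution along the
# ORF: over the P-sites within the scored span, f0u is the fraction landing
# in the uORF's own frame, tested against the null probability 1/3 with an
# upper-tail exact binomial test; PME (percentage of maximum entropy) is the
# Shannon entropy of the per-codon count distribution divided by its
# maximum, log(n_codons). score = f0u * PME, thresholded at 0.5 by default.
# For uORFs overlapping the CDS (out-of-frame and N-terminal extensions)
# only P-sites upstream of the CDS start are scored, so CDS ribosome signal
# cannot inflate the call.

#' Score one candidate uORF for active translation
#'
#' @param uorf one-row candidate data.frame (or list) with `uorf_id`,
#'   `tx_start`, `tx_end`, `category`, `cds_tx_start`.
#' @param profile the transcript's `psite_profile` (or `NULL` for none).
#' @param min_reads minimum P-sites inside the scored span for an active
#'   call (default 10).
#' @param score_threshold minimum score for an active call (default 0.5).
#' @param alpha significance level for the periodicity test (default 0.05).
#' @return one-row data.frame: `uorf_id`, `n_psites`, `f0u`,
#'   `periodicity_p`, `pme`, `score`, `active`, `truncated` (TRUE when the
#'   scored span was cut at the CDS start).
#' @export
score_uorf <- function(uorf, profile, min_reads = 10L,
                       score_threshold = 0.5, alpha = 0.05) {
  tx_start <- uorf$tx_start
  scored_end <- if (uorf$category == "non_overlapping") uorf$tx_end - 3L
                else min(uorf$tx_end, uorf$cds_tx_start)
  truncated <- uorf$category != "non_overlapping"
  res <- data.frame(uorf_id = uorf$uorf_id, n_psites = 0L, f0u = NA_real_,
                    periodicity_p = NA_real_, pme = NA_real_, score = 0,
                    active = FALSE, truncated = truncated,
                    stringsAsFactors = FALSE)
  if (is.null(profile) || scored_end <= tx_start) return(res)
  cnt <- profile$counts
  sel <- cnt$pos >= tx_start & cnt$pos < scored_end
  if (!any(sel)) return(res)
  pos <- cnt$pos[sel]; w <- cnt$count[sel]
  n <- sum(w)
  k <- sum(w[(pos - tx_start) %% 3L == 0L])
  f0u <- k / n
  pval <- stats::binom.test(k, n, p = 1 / 3,
                            alternative = "greater")$p.value
  n_codons <- as.integer(ceiling((scored_end - tx_start) / 3))
  if (n_codons <= 1L) {
    pme <- 1
  } else {
    cj <- rowsum(w, (pos - tx_start) %/% 3L)[, 1L]
    q <- cj / n                      # zero-count codons contribute 0*log 0 = 0
    H <- -sum(q * log(q))
    pme <- H / log(n_codons)
  }
  score <- f0u * pme
  res$n_psites <- n
  res$f0u <- f0u
  res$periodicity_p <- pval
  res$pme <- pme
  res$score <- score
  res$active <- n >= min_reads && pval < alpha && score >= score_threshold
  res
}

#' Call active translation for all candidates of a sample
#'
#' Scores every candidate against its transcript's P-site profile and flags
#' representative uORFs within each shared-stop group of active calls.
#'
#' @param candidates candidate data.frame (see [enumerate_candidates()]).
#' @param profiles named list of `psite_profile` objects.
#' @param sample_id label recorded in the output.
#' @inheritParams score_uorf
#' @return calls data.frame: candidate columns joined with the score fields,
#'   `representative` and `sample_id`.
#' @export
call_uorfs <- function(candidates, profiles, sample_id = "sample",
                       min_reads = 10L, score_threshold = 0.5,
                       alpha = 0.05) {
  if (nrow(candidates) == 0L) {
    out <- cbind(candidates,
                 data.frame(n_psites = integer(0), f0u = numeric(0),
                            periodicity_p = numeric(0), pme = numeric(0),
                            score = numeric(0), active = logical(0),
                            truncated = logical(0)))
    out$representative <- logical(0)
    out$sample_id <- character(0)
    return(out)
  }
  scored <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    u <- candidates[i, , drop = FALSE]
    score_uorf(u, profiles[[u$transcript_id]], min_reads = min_reads,
               score_threshold = score_threshold, alpha = alpha)
  }))
  out <- cbind(candidates, scored[, setdiff(names(scored), "uorf_id"),
                                  drop = FALSE])
  out$representative <- FALSE
  out$sample_id <- sample_id
  # representative selection per (transcript, shared stop) among active calls
  act <- which(out$active)
  if (length(act) > 0L) {
    grp <- split(act, paste(out$transcript_id[act], out$tx_end[act]))
    for (idx in grp) {
      sub <- out[idx, , drop = FALSE]
      rep_flag <- select_representative(sub, profiles[[sub$transcript_id[1L]]])
      out$representative[idx] <- rep_flag
    }
  }
  rownames(out) <- NULL
  out
}

#' Select the representative uORF within a shared-stop group
#'
#' Candidates are ordered with AUG starts first (by ascending start
#' position), then near-cognate starts (same order). Starting from the
#' first, selection advances to the next candidate whenever zero P-sites
#' fall between the current and the next start; the first candidate that
#' fails to advance (or the last, if all gaps are empty) is the
#' representative. Exactly one representative per group.
#'
#' @param group calls (or candidates) data.frame sharing one transcript and
#'   stop codon; must have `tx_start` and `start_codon`.
#' @param profile the transcript's `psite_profile`.
#' @return logical vector along `group` rows flagging the representative.
#' @export
select_representative <- function(group, profile) {
  n <- nrow(group)
  if (n == 0L) return(logical(0))
  ord <- order(group$start_codon != "ATG", group$tx_start)
  i <- 1L
  while (i < n) {
    a <- group$tx_start[ord[i]]
    b <- group$tx_start[ord[i + 1L]]
    gap <- psites_in(profile, min(a, b), max(a, b))
    if (gap == 0L) i <- i + 1L else break
  }
  flag <- logical(n)
  flag[ord[i]] <- TRUE
  flag
}

#' Aggregate uORF calls across samples
#'
#' @param per_sample_calls list of calls data.frames (one per sample, with
#'   distinct `sample_id`s), sharing the uorf_id namespace (typically after
#'   [collapse_isoforms()]).
#' @return data.frame with one row per uORF: `n_samples_active`,
#'   comma-separated active `samples`, `max_score`, `n_samples_representative`,
#'   ordered by transcript then start position. uORFs never active are
#'   retained with `n_samples_active = 0`.
#' @export
aggregate_samples <- function(per_sample_calls) {
  all <- do.call(rbind, per_sample_calls)
  pieces <- split(seq_len(nrow(all)), all$uorf_id)
  rows <- lapply(pieces, function(idx) {
    sub <- all[idx, , drop = FALSE]
    act <- sub[sub$active, , drop = FALSE]
    first <- sub[1L, c("uorf_id", "transcript_id", "tx_start", "tx_end",
                       "start_codon", "category"), drop = FALSE]
    first$n_samples_active <- nrow(act)
    first$samples <- paste(sort(unique(act$sample_id), method = "radix"),
                           collapse = ",")
    first$max_score <- if (nrow(sub)) max(sub$score) else NA_real_
    first$n_samples_representative <- sum(sub$representative)
    first
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$tx_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write uORF calls as TSV
#' @param calls calls data.frame from [call_uorfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("uorf_id", "genomic_blocks", "category", "start_codon",
            "transcript_id", "tx_start", "tx_end", "kozak", "n_psites",
            "f0u", "periodicity_p", "pme", "score", "active",
            "representative", "truncated", "sample_id")
  cols <- intersect(cols, names(calls))
  df <- calls[, cols, drop = FALSE]
  for (col in c("f0u", "periodicity_p", "pme", "score"))
    if (col %in% names(df)) df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
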
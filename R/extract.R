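# Regular-expression grammar for a complete hazard-ratio report in an
# abstract: a head token (hazard ratio / HR / H.R., optionally with a
# bracketed abbreviation), "=" or ":" with optional spaces, the HR value,
# then a confidence-interval clause carrying the level ("95% CI" or
# "CI 95%" order) and the two bounds separated by a hyphen, dash, "to", or
# comma. Decimal points only; decimal commas are not parsed.
.num_re <- "[0-9]+(?:\\.[0-9]+)?"
.head_re <- "(?:hazards?\\s+ratios?(?:\\s*[\\(\\[]\\s*HR\\s*[\\)\\]])?|H\\.R\\.|\\bHR\\b)"
.ci_re <- "(?:C\\.?\\s?I\\.?|confidence\\s+intervals?)"
.bsep_re <- "(?:-|–|—|\\bto\\b|,)"

.effect_pattern <- paste0(
  .head_re, "\\s*[=:]\\s*(", .num_re, ")",           # 1: HR
  "\\s*[;,]?\\s*[\\(\\[]?\\s*",
  "(?:(", .num_re, ")\\s*%\\s*", .ci_re,             # 2: level, "95% CI"
  "|", .ci_re, "\\s*[:=,]?\\s*(", .num_re, ")\\s*%)", # 3: level, "CI 95%"
  "\\s*[:=,]?\\s*",
  "(", .num_re, ")\\s*", .bsep_re, "\\s*(", .num_re, ")" # 4: lower, 5: upper
)

# printed decimal places of a number as it appeared in text
.decimals <- function(s) {
  ifelse(grepl(".", s, fixed = TRUE),
         nchar(sub(".*\\.", "", s)), 0L)
}

#' Extract the first complete hazard-ratio report from an abstract
#'
#' Scans the text left to right for the first complete tuple consisting of a
#' hazard ratio, the confidence level, and the lower and upper confidence
#' bounds. Matching is case-insensitive and tolerant of the common reporting
#' variants ("HR=2.3", "hazard ratio: 2.3", "H.R.: 2.3", bracketed "(HR)",
#' "95% CI 1.5-3.4", "CI 95%: 1.5 to 3.4", ...). A tuple is only returned
#' when all four numbers are present: a hazard ratio coupled with a p-value
#' but no interval is ignored, as is "HR" used for heart rate without an
#' accompanying interval. If several complete tuples occur, only the first
#' one (in reading order) is kept.
#'
#' The printed number of decimal places of the hazard ratio and of each
#' bound is recorded at parse time; the screening step
#' ([screen_effect()]) needs it to judge rounding consistency.
#'
#' @param abstract Length-1 character; may be empty.
#' @return A list of class `"extracted_effect"` with elements `hr`, `level`,
#'   `hr_lower`, `hr_upper`, `decimals_hr`, `decimals_lower`,
#'   `decimals_upper`, or `NULL` when no complete tuple is present.
#' @examples
#' extract_first_effect("Cox model: HR: 2.3 (95% CI: 1.5-3.4), p<0.01.")
#' extract_first_effect("hazard ratio = 2.3, p = 0.01")  # NULL: no interval
#' @export
extract_first_effect <- function(abstract) {
  stopifnot(length(abstract) == 1L)
  if (is.na(abstract) || !nzchar(abstract)) return(NULL)
  m <- regexpr(.effect_pattern, abstract, perl = TRUE, ignore.case = TRUE)
  if (m == -1L) return(NULL)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(i) {
    if (cs[1L, i] > 0L) substr(abstract, cs[1L, i], cs[1L, i] + cl[1L, i] - 1L)
    else NA_character_
  }
  hr_s <- grab(1L)
  lvl_s <- if (!is.na(grab(2L))) grab(2L) else grab(3L)
  lo_s <- grab(4L)
  up_s <- grab(5L)
  structure(list(
    hr = as.numeric(hr_s),
    level = as.numeric(lvl_s),
    hr_lower = as.numeric(lo_s),
    hr_upper = as.numeric(up_s),
    decimals_hr = .decimals(hr_s),
    decimals_lower = .decimals(lo_s),
    decimals_upper = .decimals(up_s)
  ), class = "extracted_effect")
}

# value as it would appear printed at d decimal places
.printed <- function(x, d) formatC(x, format = "f", digits = d)

# decimal places implied by the shortest decimal representation of x
.infer_decimals <- function(x) .decimals(as.character(x))

#' Validity screening of an extracted hazard-ratio tuple
#'
#' Applies the four validity checks used before pooling:
#' \describe{
#'   \item{LEVEL_RANGE}{the confidence level must lie strictly between 0
#'     and 100;}
#'   \item{NONPOSITIVE}{HR and both bounds must be strictly positive (the
#'     hazard-ratio scale is (0, Inf));}
#'   \item{MIDPOINT}{the log HR must sit in the middle of the log bounds,
#'     up to the slack that rounding each printed number to its reported
#'     decimal places can introduce;}
#'   \item{BOUND_COLLISION}{the HR must not equal either bound as printed
#'     (a collision indicates the interval degenerated under rounding).}
#' }
#'
#' The MIDPOINT tolerance is the first-order propagation of half-ULP
#' rounding of each printed number through the logarithm:
#' `0.5*10^-d_hr/hr + 0.25*(10^-d_l/lower + 10^-d_u/upper)`, where `d_*`
#' are the printed decimal places. BOUND_COLLISION compares the numbers as
#' printed at their own decimal places, so "2.3" and "2.30" do not collide.
#' An interval whose bounds are reversed (lower > upper) cannot bracket the
#' HR as reported and is flagged under MIDPOINT.
#'
#' @param hr Extracted hazard ratio, or an `"extracted_effect"` object from
#'   [extract_first_effect()] (in which case the remaining arguments are
#'   taken from it).
#' @param level Confidence level in percent.
#' @param hr_lower,hr_upper Confidence bounds on the HR scale.
#' @param decimals_hr,decimals_lower,decimals_upper Printed decimal places;
#'   when `NULL` they are inferred from the shortest decimal representation
#'   of the corresponding value.
#' @return A list of class `"screen_report"` with elements `passed`
#'   (logical) and `reason_codes` (character vector, empty iff passed).
#' @examples
#' screen_effect(2.0, 95, 1.0, 4.0)$passed        # TRUE: exact log midpoint
#' screen_effect(2.3, 95, 2.3, 3.4)$reason_codes  # "BOUND_COLLISION"
#' @export
screen_effect <- function(hr, level, hr_lower, hr_upper,
                          decimals_hr = NULL, decimals_lower = NULL,
                          decimals_upper = NULL) {
  if (is.list(hr)) {
    e <- hr
    hr <- e$hr; level <- e$level
    hr_lower <- e$hr_lower; hr_upper <- e$hr_upper
    decimals_hr <- e$decimals_hr
    decimals_lower <- e$decimals_lower
    decimals_upper <- e$decimals_upper
  }
  d_hr <- if (is.null(decimals_hr)) .infer_decimals(hr) else decimals_hr
  d_lo <- if (is.null(decimals_lower)) .infer_decimals(hr_lower) else decimals_lower
  d_up <- if (is.null(decimals_upper)) .infer_decimals(hr_upper) else decimals_upper

  codes <- character(0)
  if (!isTRUE(level > 0 && level < 100)) codes <- c(codes, "LEVEL_RANGE")
  positive <- isTRUE(hr > 0) && isTRUE(hr_lower > 0) && isTRUE(hr_upper > 0)
  if (!positive) codes <- c(codes, "NONPOSITIVE")
  if (positive) {
    dev <- abs(log(hr) - 0.5 * (log(hr_lower) + log(hr_upper)))
    tol <- 0.5 * 10^(-d_hr) / hr +
      0.25 * (10^(-d_lo) / hr_lower + 10^(-d_up) / hr_upper)
    if (hr_lower > hr_upper || dev > tol) codes <- c(codes, "MIDPOINT")
    hr_p <- .printed(hr, d_hr)
    if (identical(hr_p, .printed(hr_lower, d_lo)) ||
        identical(hr_p, .printed(hr_upper, d_up))) {
      codes <- c(codes, "BOUND_COLLISION")
    }
  }
  structure(list(passed = length(codes) == 0L, reason_codes = codes),
            class = "screen_report")
}

#' Mine a corpus of abstracts for hazard-ratio effects
#'
#' Runs the full mining stage over an article table: each article is
#' allocated to subfields by its journal name ([allocate_subfields()]), its
#' abstract is scanned for the first complete HR + CI tuple
#' ([extract_first_effect()]), and the tuple is screened
#' ([screen_effect()]). Articles allocated to several subfields contribute
#' the same tuple to each subfield's corpus. Articles whose journal matches
#' no subfield are dropped.
#'
#' @param articles Data frame with columns `article_id`, `journal`,
#'   `abstract`.
#' @param journal_lists Data frame with columns `subfield`, `journal`, or a
#'   prebuilt index from [build_subfield_index()].
#' @param keep_failed Keep rows for tuples that failed screening (and for
#'   allocated articles with no extractable tuple)? Default `TRUE`; the
#'   `passed` column distinguishes them.
#' @return A list of class `"mined_corpus"`:
#'   \describe{
#'     \item{effects}{one row per (article, subfield) with the extracted
#'       tuple, printed decimal places, `passed`, and `reason_codes`
#'       (semicolon-separated); extraction failures carry `NA` tuples when
#'       `keep_failed = TRUE`.}
#'     \item{counts}{per (subfield, journal) counts of articles allocated,
#'       matched (tuple extracted), and considered (passed screening).}
#'   }
#' @export
mine_abstracts <- function(articles, journal_lists, keep_failed = TRUE) {
  stopifnot(is.data.frame(articles),
            all(c("article_id", "journal", "abstract") %in% names(articles)))
  if (anyDuplicated(articles$article_id))
    stop("article_id must be unique within a corpus")
  index <- if (is.data.frame(journal_lists)) build_subfield_index(journal_lists)
           else journal_lists

  rows <- vector("list", nrow(articles))
  for (i in seq_len(max(nrow(articles), 0L))) {
    subs <- allocate_subfields(articles$journal[i], index)
    if (length(subs) == 0L) next
    eff <- extract_first_effect(articles$abstract[i])
    journal_canon <- normalize_journal_name(articles$journal[i])
    if (is.null(eff)) {
      rows[[i]] <- data.frame(
        article_id = articles$article_id[i], subfield = subs,
        journal = journal_canon,
        hr = NA_real_, level = NA_real_,
        hr_lower = NA_real_, hr_upper = NA_real_,
        decimals_hr = NA_integer_, decimals_lower = NA_integer_,
        decimals_upper = NA_integer_,
        matched = FALSE, passed = FALSE, reason_codes = "",
        stringsAsFactors = FALSE)
    } else {
      rep_ <- screen_effect(eff)
      rows[[i]] <- data.frame(
        article_id = articles$article_id[i], subfield = subs,
        journal = journal_canon,
        hr = eff$hr, level = eff$level,
        hr_lower = eff$hr_lower, hr_upper = eff$hr_upper,
        decimals_hr = eff$decimals_hr, decimals_lower = eff$decimals_lower,
        decimals_upper = eff$decimals_upper,
        matched = TRUE, passed = rep_$passed,
        reason_codes = paste(rep_$reason_codes, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(effects)) {
    effects <- data.frame(
      article_id = character(0), subfield = character(0),
      journal = character(0), hr = numeric(0), level = numeric(0),
      hr_lower = numeric(0), hr_upper = numeric(0),
      decimals_hr = integer(0), decimals_lower = integer(0),
      decimals_upper = integer(0), matched = logical(0),
      passed = logical(0), reason_codes = character(0),
      stringsAsFactors = FALSE)
  }
  rownames(effects) <- NULL

  counts <- .mining_counts(effects)
  if (!keep_failed) effects <- effects[effects$passed, , drop = FALSE]
  structure(list(effects = effects, counts = counts),
            class = "mined_corpus")
}

.mining_counts <- function(effects) {
  if (nrow(effects) == 0L) {
    return(data.frame(subfield = character(0), journal = character(0),
                      allocated = integer(0), matched = integer(0),
                      considered = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    cbind(allocated = rep(1L, nrow(effects)),
          matched = as.integer(effects$matched),
          considered = as.integer(effects$passed)),
    by = list(subfield = effects$subfield, journal = effects$journal),
    FUN = sum)
  agg <- agg[order(agg$subfield, agg$journal), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.mined_corpus <- function(x, ...) {
  cat("Mined hazard-ratio corpus\n")
  by_sub <- split(x$counts, x$counts$subfield)
  for (s in names(by_sub)) {
    cs <- by_sub[[s]]
    cat(sprintf("  %-40s allocated %5d  matched %5d  considered %5d\n",
                s, sum(cs$allocated), sum(cs$matched), sum(cs$considered)))
  }
  invisible(x)
}

#' Article retention proportions across processing steps
#'
#' For each (subfield, journal) pair, computes the proportion of articles
#' surviving each processing transition: `S1 = matched / allocated` (the
#' extraction step) and `S2 = considered / matched` (the screening step).
#' Pairs with a zero denominator at either step are dropped, since the
#' corresponding proportion is undefined.
#'
#' @param counts Data frame with columns `subfield`, `journal`, `allocated`,
#'   `matched`, `considered` (e.g. the `counts` element of
#'   [mine_abstracts()]).
#' @return The input rows with non-zero denominators, with `S1` and `S2`
#'   columns appended.
#' @export
retention_table <- function(counts) {
  stopifnot(all(c("allocated", "matched", "considered") %in% names(counts)))
  if (any(counts$allocated < 0 | counts$matched < 0 | counts$considered < 0))
    stop("counts must be non-negative")
  keep <- counts$allocated > 0 & counts$matched > 0
  out <- counts[keep, , drop = FALSE]
  out$S1 <- out$matched / out$allocated
  out$S2 <- out$considered / out$matched
  rownames(out) <- NULL
  out
}
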
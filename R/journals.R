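#' Canonicalize a journal name
#'
#' Journal names coming from different bibliographic databases disagree on
#' punctuation, ampersands, case, and the placement of a leading article
#' ("Lancet Oncology, The" vs "The Lancet Oncology"). This function maps all
#' such variants to one canonical form so that journal lists from different
#' sources can be matched by simple string equality.
#'
#' The cleaning rules are applied in this order:
#' 1. replace `&amp;` and `&` with `AND`;
#' 2. drop every character that is neither alphabetic nor whitespace;
#' 3. move a trailing "The" (left over from "..., The") to the front;
#' 4. collapse runs of whitespace and trim;
#' 5. convert to upper case.
#'
#' The order matters: ampersands must be replaced before the punctuation
#' strip (step 2 would silently delete them), and the "The" repositioning
#' runs on the already-stripped string, where the comma of "..., The" is
#' gone. The function is idempotent.
#'
#' @param raw Character vector of raw journal names. `NA` is treated as an
#'   empty string.
#' @return Character vector of canonical (upper-case) journal names.
#' @examples
#' normalize_journal_name("Lancet Oncology, The")  # "THE LANCET ONCOLOGY"
#' normalize_journal_name("Heart & Lung")          # "HEART AND LUNG"
#' @export
normalize_journal_name <- function(raw) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- gsub("&amp;", " AND ", x, fixed = TRUE)
  x <- gsub("&", " AND ", x, fixed = TRUE)
  x <- gsub("[^[:alpha:][:space:]]", "", x)
  trailing_the <- grepl("[[:space:]]+[Tt][Hh][Ee][[:space:]]*$", x)
  x[trailing_the] <- paste(
    "The", sub("[[:space:]]+[Tt][Hh][Ee][[:space:]]*$", "", x[trailing_the])
  )
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("^ ", "", sub(" $", "", x))
  toupper(x)
}

#' Build a subfield index from a journal list table
#'
#' @param journal_lists Data frame with columns `subfield` and `journal`
#'   (raw journal names; they are canonicalized internally).
#' @return A named list mapping each subfield to the character vector of
#'   canonical journal names it contains. A journal may appear under several
#'   subfields.
#' @seealso [normalize_journal_name()], [allocate_subfields()]
#' @export
build_subfield_index <- function(journal_lists) {
  stopifnot(is.data.frame(journal_lists),
            all(c("subfield", "journal") %in% names(journal_lists)))
  canon <- normalize_journal_name(journal_lists$journal)
  idx <- split(canon, as.character(journal_lists$subfield))
  lapply(idx, unique)
}

#' Allocate an article to biomedical subfields by its journal
#'
#' An article belongs to every subfield whose journal list contains the
#' canonical form of the article's journal name; shared journals (e.g. a
#' pain journal listed under both anesthesiology and neurology) therefore
#' allocate the same article to several subfields. Unknown journals yield an
#' empty allocation.
#'
#' @param journal_raw Raw journal name of the article (length-1 character).
#' @param index Subfield index from [build_subfield_index()].
#' @return Character vector of subfield names (possibly empty).
#' @export
allocate_subfields <- function(journal_raw, index) {
  stopifnot(is.list(index))
  canon <- normalize_journal_name(journal_raw)
  hit <- vapply(index, function(set) canon %in% set, logical(1))
  names(index)[hit]
}
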
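#' Read an article table from CSV
#'
#' Expects UTF-8 CSV with a header row and columns `article_id`, `journal`,
#' `abstract`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of articles.
#' @export
read_articles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  need <- c("article_id", "journal", "abstract")
  if (!all(need %in% names(df)))
    stop("articles CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read subfield journal lists from CSV
#'
#' Expects columns `subfield`, `journal`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of journal lists.
#' @export
read_journal_lists <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("subfield", "journal") %in% names(df)))
    stop("journal list CSV needs columns: subfield, journal")
  df
}

#' Write a prior specification as a plain-text key-value file
#'
#' @param prior A `"cox_prior"` object.
#' @param path Output path.
#' @param subfield Optional subfield label to record.
#' @export
write_prior_spec <- function(prior, path, subfield = NA) {
  lines <- c(
    if (!is.na(subfield)) paste0("subfield: ", subfield),
    paste0("family: ", prior$family),
    paste0("mu: ", format(prior$mu, digits = 15)),
    paste0("sigma: ", format(prior$sigma, digits = 15)),
    paste0("truncation: ", prior$truncation),
    paste0("n_assumed: ", prior$n_assumed),
    paste0("N_studies: ", prior$n_studies))
  writeLines(lines, path)
  invisible(path)
}

#' Read a prior specification written by [write_prior_spec()]
#'
#' @param path Path to the key-value file.
#' @return A `"cox_prior"` object.
#' @export
read_prior_spec <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  cox_prior(mu = as.numeric(vals[["mu"]]),
            sigma = as.numeric(vals[["sigma"]]),
            truncation = vals[["truncation"]],
            n_assumed = suppressWarnings(as.numeric(vals[["n_assumed"]])),
            n_studies = suppressWarnings(as.integer(vals[["N_studies"]])))
}

#' Run the full prior-elicitation pipeline
#'
#' Ties the stages together: mine abstracts for hazard-ratio tuples
#' ([mine_abstracts()]), screen them, convert the survivors of each
#' subfield to a (b, SE) corpus ([effects_to_corpus()]), pool each corpus
#' into a zero-centered Normal prior ([prior_from_corpus()]), and
#' optionally run the sample-size sensitivity analysis
#' ([sensitivity_sigma()]). When `out_dir` is given, the effects table,
#' one prior spec per subfield, and the run manifest are written there as
#' plain-text artifacts carrying the seed in a header comment.
#'
#' An empty article table yields a zero-count manifest and a warning, but
#' no prior. A subfield in which records were mined but none survived
#' screening raises an error at the pooling stage (a prior cannot be built
#' from N = 0 studies).
#'
#' @param articles Article data frame (or path to a CSV readable by
#'   [read_articles()]).
#' @param journal_lists Journal list data frame (or path to a CSV).
#' @param out_dir Optional output directory for artifacts.
#' @param n_assumed Common per-study sample size for pooling (default 200).
#' @param sens_reps Repetitions for the sensitivity analysis per subfield;
#'   0 (default) skips it.
#' @param seed Seed recorded in the manifest and used for the sensitivity
#'   draws.
#' @return A list of class `"pipeline_run"`: `manifest` (per-subfield
#'   allocated/matched/considered counts), `effects`, `priors` (named list
#'   of `"cox_prior"`), `sensitivity` (named list or `NULL`), `seed`.
#' @export
run_pipeline <- function(articles, journal_lists, out_dir = NULL,
                         n_assumed = 200, sens_reps = 0, seed = 1) {
  if (is.character(articles)) articles <- read_articles(articles)
  if (is.character(journal_lists)) journal_lists <- read_journal_lists(journal_lists)

  mined <- mine_abstracts(articles, journal_lists)
  counts <- mined$counts
  manifest <- if (nrow(counts)) {
    agg <- stats::aggregate(counts[c("allocated", "matched", "considered")],
                            by = list(subfield = counts$subfield), FUN = sum)
    agg[order(agg$subfield), , drop = FALSE]
  } else {
    data.frame(subfield = character(0), allocated = integer(0),
               matched = integer(0), considered = integer(0))
  }

  priors <- list(); sens <- NULL
  if (nrow(mined$effects) == 0L) {
    warning("no articles were allocated to any subfield; no prior emitted")
  } else if (!any(mined$effects$passed)) {
    stop("pooling stage: every mined record failed screening (N = 0 in all subfields)")
  } else {
    subfields <- sort(unique(mined$effects$subfield[mined$effects$passed]))
    priors <- lapply(subfields, function(s) {
      corpus <- effects_to_corpus(mined$effects, subfield = s)
      prior_from_corpus(corpus, n = n_assumed)
    })
    names(priors) <- subfields
    if (sens_reps > 0) {
      sens <- lapply(subfields, function(s) {
        corpus <- effects_to_corpus(mined$effects, subfield = s)
        sensitivity_sigma(corpus, reps = sens_reps, seed = seed)
      })
      names(sens) <- subfields
    }
  }

  run <- structure(list(manifest = manifest, effects = mined$effects,
                        priors = priors, sensitivity = sens, seed = seed),
                   class = "pipeline_run")
  if (!is.null(out_dir)) .write_run_artifacts(run, out_dir)
  run
}

.write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# coxprior run, seed=%s", run$seed)
  eff_path <- file.path(out_dir, "effects.csv")
  con <- file(eff_path, "w")
  writeLines(hdr, con)
  utils::write.csv(run$effects, con, row.names = FALSE)
  close(con)
  man_path <- file.path(out_dir, "manifest.csv")
  con <- file(man_path, "w")
  writeLines(hdr, con)
  utils::write.csv(run$manifest, con, row.names = FALSE)
  close(con)
  for (s in names(run$priors)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", s)
    write_prior_spec(run$priors[[s]],
                     file.path(out_dir, paste0("prior_", safe, ".txt")),
                     subfield = s)
  }
  if (!is.null(run$sensitivity)) {
    for (s in names(run$sensitivity)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", s)
      utils::write.csv(
        data.frame(rep = seq_along(run$sensitivity[[s]]$sigmas),
                   sigma = run$sensitivity[[s]]$sigmas),
        file.path(out_dir, paste0("sensitivity_", safe, ".csv")),
        row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("coxprior pipeline run (seed", x$seed, ")\n")
  if (nrow(x$manifest)) {
    for (i in seq_len(nrow(x$manifest))) {
      m <- x$manifest[i, ]
      sig <- if (m$subfield %in% names(x$priors))
        sprintf("sigma_p = %.3f", x$priors[[m$subfield]]$sigma) else "no prior"
      cat(sprintf("  %-35s %5d allocated / %5d matched / %5d considered  %s\n",
                  m$subfield, m$allocated, m$matched, m$considered, sig))
    }
  } else cat("  (no articles allocated)\n")
  invisible(x)
}
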
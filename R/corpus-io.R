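#' Read an abstract corpus
#'
#' Reads citations from one of three dialects into a tibble with columns
#' `pmid`, `title`, `abstract`. Records lacking an abstract are retained
#' with an empty abstract and a warning, since a title alone can still be
#' classified.
#'
#' @param path Path to the corpus file.
#' @param format One of `"medline"` (PMID/TI/AB tagged flat file),
#'   `"pubmed-xml"` (PubmedArticleSet XML) or `"tsv"` (columns pmid, title,
#'   abstract).
#' @return A tibble, one row per citation.
#' @export
read_abstracts <- function(path, format = c("medline", "pubmed-xml", "tsv")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  out <- switch(format,
    "medline" = read_medline(path),
    "pubmed-xml" = read_pubmed_xml(path),
    "tsv" = {
      tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                             na = character(), progress = FALSE)
      need <- c("pmid", "title", "abstract")
      if (!all(need %in% names(tbl))) {
        abort(paste0("TSV corpus must have columns pmid, title, abstract; got: ",
                     paste(names(tbl), collapse = ", ")))
      }
      tbl %>% select(dplyr::all_of(need))
    })
  out <- out %>%
    mutate(pmid = as.character(.data$pmid),
           title = as.character(.data$title),
           abstract = dplyr::coalesce(as.character(.data$abstract), ""))
  if (any(is.na(out$pmid) | out$pmid == "")) {
    abort(paste0("malformed record(s) without a PMID at row(s): ",
                 paste(which(is.na(out$pmid) | out$pmid == ""), collapse = ", ")))
  }
  dups <- out$pmid[duplicated(out$pmid)]
  if (length(dups)) {
    abort(paste0("duplicate PMID(s) in corpus: ",
                 paste(unique(dups), collapse = ", ")))
  }
  n_empty <- sum(out$abstract == "")
  if (n_empty > 0) {
    warn(paste0(n_empty, " record(s) have no abstract; kept with empty text"))
  }
  out
}

read_medline <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  recs <- list(); cur <- NULL; tag <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    tibble(pmid = paste(cur$PMID %||% NA_character_, collapse = " "),
           title = paste(cur$TI %||% "", collapse = " "),
           abstract = paste(cur$AB %||% "", collapse = " "))
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) {
      recs[[length(recs) + 1L]] <- flush(cur); cur <- NULL; tag <- NULL
      next
    }
    if (grepl("^[A-Z]{1,4}\\s*- ", ln)) {
      tag <- sub("^([A-Z]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z]{1,4}\\s*- ", "", ln)
      if (is.null(cur)) cur <- list()
      cur[[tag]] <- c(cur[[tag]], val)
    } else if (grepl("^\\s{2,}", ln) && !is.null(tag)) {
      n <- length(cur[[tag]])
      cur[[tag]][n] <- paste(cur[[tag]][n], trimws(ln))
    } else {
      abort(paste0("malformed MEDLINE line (no tag): '", substr(ln, 1, 40), "'"))
    }
  }
  recs[[length(recs) + 1L]] <- flush(cur)
  out <- bind_rows(recs)
  if (nrow(out) == 0) abort("no MEDLINE records found")
  out
}

read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  if (length(arts) == 0) abort("no PubmedArticle records found in XML")
  purrr::map_dfr(seq_along(arts), function(i) {
    a <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID | ./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    if (is.na(pmid) || pmid == "") {
      abort(paste0("malformed PubMed XML record at index ", i, ": missing PMID"))
    }
    tibble(pmid = pmid,
           title = if (is.na(title)) "" else title,
           abstract = paste(xml2::xml_text(abst), collapse = " "))
  })
}

#' Write an abstract corpus
#'
#' Inverse of [read_abstracts()]; round-trips losslessly for all three
#' dialects (whitespace-normalised text).
#'
#' @param corpus Tibble with `pmid`, `title`, `abstract`.
#' @inheritParams read_abstracts
#' @return `path`, invisibly.
#' @export
write_abstracts <- function(corpus, path, format = c("medline", "pubmed-xml", "tsv")) {
  format <- arg_match(format)
  switch(format,
    "medline" = {
      blocks <- purrr::pmap_chr(corpus, function(pmid, title, abstract, ...) {
        paste0("PMID- ", pmid, "\n", "TI  - ", title,
               if (nzchar(abstract)) paste0("\nAB  - ", abstract) else "")
      })
      readr::write_lines(paste(blocks, collapse = "\n\n"), path)
    },
    "tsv" = readr::write_tsv(corpus, path, progress = FALSE),
    "pubmed-xml" = {
      root <- xml2::xml_new_root("PubmedArticleSet")
      for (i in seq_len(nrow(corpus))) {
        art <- xml2::xml_add_child(root, "PubmedArticle")
        cit <- xml2::xml_add_child(art, "MedlineCitation")
        xml2::xml_add_child(cit, "PMID", corpus$pmid[i])
        a <- xml2::xml_add_child(cit, "Article")
        xml2::xml_add_child(a, "ArticleTitle", corpus$title[i])
        if (nzchar(corpus$abstract[i])) {
          ab <- xml2::xml_add_child(a, "Abstract")
          xml2::xml_add_child(ab, "AbstractText", corpus$abstract[i])
        }
      }
      xml2::write_xml(root, path)
    })
  invisible(path)
}

#' Read a label table
#'
#' Tab-separated with header `PMID LEVEL0 LEVEL1 LEVEL2 LEVEL3` and literal
#' `NA` for absent levels. `LEVEL0` is `curatable` or `uncuratable`.
#'
#' @param path Path to the TSV.
#' @param taxonomy Optional [taxonomy]; when supplied, every label path is
#'   validated against it (see [validate_labels()]).
#' @return A tibble with columns `pmid`, `level0`, `level1`, `level2`,
#'   `level3`.
#' @export
read_label_table <- function(path, taxonomy = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  need <- c("PMID", "LEVEL0", "LEVEL1", "LEVEL2", "LEVEL3")
  if (!all(need %in% names(tbl))) {
    abort(paste0("label table must have header ", paste(need, collapse = " "),
                 "; got: ", paste(names(tbl), collapse = ", ")))
  }
  out <- tbl %>%
    select(dplyr::all_of(need)) %>%
    rename(pmid = "PMID", level0 = "LEVEL0", level1 = "LEVEL1",
           level2 = "LEVEL2", level3 = "LEVEL3")
  bad0 <- !out$level0 %in% c("curatable", "uncuratable")
  if (any(bad0)) {
    abort(paste0("invalid LEVEL0 value for PMID ",
                 paste(out$pmid[bad0], collapse = ", "),
                 " (must be curatable/uncuratable)"))
  }
  if (!is.null(taxonomy)) validate_labels(out, taxonomy)
  out
}

#' Write a label table
#'
#' @param labels Label tibble (`pmid`, `level0`, `level1`..`level3`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  out <- labels %>%
    select("pmid", "level0", "level1", "level2", "level3") %>%
    rename(PMID = "pmid", LEVEL0 = "level0", LEVEL1 = "level1",
           LEVEL2 = "level2", LEVEL3 = "level3")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Join abstracts to their labels
#'
#' Inner join on PMID; the counts of unmatched records on both sides are
#' reported as a message and attached as the `"unmatched"` attribute.
#'
#' @param abstracts Corpus tibble from [read_abstracts()].
#' @param labels Label tibble from [read_label_table()].
#' @return The joined tibble (`pmid`, `title`, `abstract`, `level0`..`level3`).
#' @export
join_corpus <- function(abstracts, labels) {
  joined <- inner_join(abstracts, labels, by = "pmid")
  if (nrow(joined) == 0) abort("no overlap between corpus and label PMIDs")
  n_unlabeled <- nrow(anti_join(abstracts, labels, by = "pmid"))
  n_untexted <- nrow(anti_join(labels, abstracts, by = "pmid"))
  if (n_unlabeled || n_untexted) {
    inform(paste0("join_corpus: ", n_unlabeled, " abstract(s) without labels, ",
                  n_untexted, " label(s) without abstracts dropped"))
  }
  attr(joined, "unmatched") <- c(abstracts = n_unlabeled, labels = n_untexted)
  joined
}

# the classification text of a record: title and abstract, space-joined
classification_text <- function(corpus) {
  trimws(paste(corpus$title, corpus$abstract))
}
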
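# Lexicon loaders and gene orthographic variant expansion.

CANCER_KEYWORDS <- c("cancer", "tumor", "tumour", "neoplasm",
                     "carcinogenesis", "tumorigenesis", "metastasis")

#' Load the cancer lexicon
#'
#' Assembles the four resources behind the cancer tagger: canonical
#' multi-word names (matched case-insensitively, longest first),
#' case-sensitive abbreviations with expansions, anatomical tumor-site
#' terms, and the fixed cancer-keyword list (\code{cancer}, \code{tumor},
#' \code{tumour}, \code{neoplasm}, \code{carcinogenesis},
#' \code{tumorigenesis}, \code{metastasis}).  Packaged fixtures are used
#' unless paths are supplied.
#'
#' @param names_path TSV with a \code{name} column of canonical names.
#' @param abbreviations_path TSV with \code{acronym}, \code{expansion}.
#' @param sites_path TSV with a \code{site} column.
#' @return an object of class \code{cancer_lexicon}.
#' @export
cancer_lexicon <- function(names_path = NULL, abbreviations_path = NULL,
                           sites_path = NULL) {
  ext <- function(f) system.file("extdata", f, package = "methrelex")
  if (is.null(names_path)) names_path <- ext("cancer_names.tsv")
  if (is.null(abbreviations_path)) abbreviations_path <- ext("cancer_abbreviations.tsv")
  if (is.null(sites_path)) sites_path <- ext("tumor_sites.tsv")
  nm <- read.delim(names_path, stringsAsFactors = FALSE)
  ab <- read.delim(abbreviations_path, stringsAsFactors = FALSE)
  st <- read.delim(sites_path, stringsAsFactors = FALSE)
  structure(
    list(canonical_names = tolower(nm$name),
         abbreviations = setNames(ab$expansion, ab$acronym),
         site_terms = tolower(st$site),
         keyword_terms = CANCER_KEYWORDS),
    class = "cancer_lexicon"
  )
}

#' Generate orthographic variants of a gene symbol
#'
#' Applies simple surface rules — hyphen insertion at the trailing
#' letter-to-digit boundary (\code{BRCA1} to \code{BRCA-1}), hyphen
#' removal, and upper/lower case folding — and closes the set under
#' re-application, so variants of variants add nothing new.
#'
#' @param symbol a non-empty gene symbol.
#' @return character vector of surface variants including the symbol.
#' @export
generate_variants <- function(symbol) {
  if (!nzchar(symbol)) stop("symbol must be non-empty")
  out <- symbol
  repeat {
    new <- unique(unlist(lapply(out, function(s) {
      v <- c(s, toupper(s), tolower(s), gsub("-", "", s, fixed = TRUE))
      if (grepl("^([A-Za-z]+)([0-9]+)$", s)) {
        v <- c(v, sub("^([A-Za-z]+)([0-9]+)$", "\\1-\\2", s))
      }
      v
    })))
    if (length(setdiff(new, out)) == 0) break
    out <- union(out, new)
  }
  sort(out)
}

#' Load and expand a gene lexicon
#'
#' Reads a tabular dictionary (official symbol, identifier, optional
#' pipe-separated aliases), expands each surface through
#' \code{\link{generate_variants}}, and indexes the result for
#' case-sensitive-first lookup.  Every official symbol maps to itself.
#'
#' @param path TSV with columns \code{symbol}, \code{gene_id} and
#'   optionally \code{aliases} (pipe-separated); defaults to the packaged
#'   fixture dictionary (a small curated set of methylation-studied
#'   genes, not a full genome dictionary).
#' @return an object of class \code{gene_lexicon} with \code{exact}
#'   (case-sensitive surface to id) and \code{folded} (lower-cased
#'   surface to id) maps plus \code{symbols} (id to official symbol).
#' @export
gene_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_dictionary.tsv", package = "methrelex")
  }
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("symbol", "gene_id") %in% names(d))) {
    stop("gene dictionary needs columns symbol, gene_id")
  }
  exact <- new.env(parent = emptyenv())
  folded <- new.env(parent = emptyenv())
  symbols <- new.env(parent = emptyenv())
  max_len <- 1L
  for (i in seq_len(nrow(d))) {
    id <- d$gene_id[i]
    assign(d$symbol[i], id, envir = symbols)  # temp; replaced below
    surfaces <- d$symbol[i]
    if ("aliases" %in% names(d) && nzchar(d$aliases[i]) && !is.na(d$aliases[i])) {
      surfaces <- c(surfaces, strsplit(d$aliases[i], "|", fixed = TRUE)[[1]])
    }
    for (s in surfaces) {
      for (v in generate_variants(s)) {
        if (!exists(v, envir = exact, inherits = FALSE)) assign(v, id, envir = exact)
        lv <- tolower(v)
        if (!exists(lv, envir = folded, inherits = FALSE)) assign(lv, id, envir = folded)
        nw <- length(strsplit(v, " ", fixed = TRUE)[[1]])
        if (nw > max_len) max_len <- nw
      }
    }
  }
  sym_map <- setNames(d$symbol, d$gene_id)
  structure(list(exact = exact, folded = folded, symbols = sym_map,
                 max_ngram = max_len),
            class = "gene_lexicon")
}

#' Look up a gene surface form
#'
#' Case-sensitive lookup first, then case-insensitive.
#'
#' @param lexicon a \code{\link{gene_lexicon}}.
#' @param surface the candidate surface string.
#' @return the gene identifier, or \code{NA_character_} when absent.
#' @export
gene_lookup <- function(lexicon, surface) {
  if (exists(surface, envir = lexicon$exact, inherits = FALSE)) {
    return(get(surface, envir = lexicon$exact))
  }
  lv <- tolower(surface)
  if (exists(lv, envir = lexicon$folded, inherits = FALSE)) {
    return(get(lv, envir = lexicon$folded))
  }
  NA_character_
}
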
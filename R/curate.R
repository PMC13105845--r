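# Corpus curation: ambiguity filtering and linkage-variant expansion.

# Expand one linkage token with "/" alternatives, e.g. "a2-3/6" -> c("a2-3",
# "a2-6"). The first alternative is the full linkage; later alternatives that
# are bare digits replace its trailing digit run ("a1-3/5" -> "a1-3","a1-5");
# alternatives containing "-" are taken as complete linkages.
.expandLinkage <- function(link) {
  parts <- strsplit(link, "/", fixed = TRUE)[[1L]]
  if (any(parts == ""))
    glycanStop("glycanCurationError", "malformed linkage alternatives \"%s\"", link)
  first <- parts[1L]
  stem <- sub("[0-9]+$", "", first)
  if (identical(stem, first) && length(parts) > 1L)
    glycanStop("glycanCurationError",
               "linkage \"%s\" has alternatives but no trailing position digits", link)
  out <- first
  for (p in parts[-1L]) {
    if (grepl("^[0-9]+$", p)) out <- c(out, paste0(stem, p))
    else if (grepl("-", p, fixed = TRUE)) out <- c(out, p)
    else glycanStop("glycanCurationError",
                    "cannot interpret linkage alternative \"%s\" in \"%s\"", p, link)
  }
  unique(out)
}

#' Curate a glycan corpus: reject ambiguity, expand linkage variants
#'
#' Strings containing the wildcard \code{"?"} anywhere are rejected. Strings
#' with \code{"/"} inside a linkage (e.g. \code{"NeuNAc(a2-3/6)Gal"}) are
#' expanded into the cartesian product of the admissible alternatives, each
#' expanded variant becoming an independent entry. Fully resolved strings
#' pass through unchanged. A \code{"/"} outside a linkage position is a
#' validation error and the entry is rejected with that reason.
#'
#' @param texts character vector of IUPAC-condensed strings.
#' @param maxVariants cap on expanded variants per entry (default 16); entries
#'   whose cartesian product exceeds the cap are truncated to the first
#'   \code{maxVariants} variants with a warning.
#' @return a \code{CurationReport} list with components \code{kept}
#'   (character), \code{rejected} (data.frame input/reason) and
#'   \code{expansions} (named list input -> character vector of variants).
#'   Every input lands in exactly one component.
#' @examples
#' curateCorpus(c("Gal(b1-3)GalNAc", "NeuNAc(a2-3/6)Gal", "NeuNAc(a2-?)Gal"))
#' @export
curateCorpus <- function(texts, maxVariants = 16L) {
  stopifnot(is.character(texts))
  kept <- character(0)
  rejected <- data.frame(input = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  expansions <- list()
  for (tx in texts) {
    if (grepl("?", tx, fixed = TRUE)) {
      rejected <- rbind(rejected, data.frame(
        input = tx, reason = "ambiguous symbol '?'", stringsAsFactors = FALSE))
      next
    }
    if (!grepl("/", tx, fixed = TRUE)) {
      kept <- c(kept, tx)
      next
    }
    # "/" must sit inside a "(...)" linkage; expand the cartesian product
    res <- tryCatch({
      toks <- .iupacTokens(tx)
      if (any(toks$kind == "residue" & grepl("/", toks$text, fixed = TRUE)))
        glycanStop("glycanCurationError", "'/' outside a linkage position")
      linkSel <- which(toks$kind == "link")
      alts <- lapply(toks$text[linkSel], .expandLinkage)
      variants <- ""
      for (k in seq_len(nrow(toks))) {
        piece <- switch(toks$kind[k],
                        residue = toks$text[k],
                        "[" = "[", "]" = "]",
                        link = NA_character_)
        if (is.na(piece)) {
          a <- alts[[match(k, linkSel)]]
          variants <- as.vector(vapply(a, function(x)
            paste0(variants, "(", x, ")"), character(length(variants))))
        } else {
          variants <- paste0(variants, piece)
        }
        if (length(variants) > maxVariants) {
          warning(sprintf("entry \"%s\": variant cap %d reached, truncating", tx, maxVariants))
          variants <- variants[seq_len(maxVariants)]
        }
      }
      variants
    }, glycanError = function(e) e)
    if (inherits(res, "condition")) {
      rejected <- rbind(rejected, data.frame(
        input = tx, reason = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      expansions[[tx]] <- res
    }
  }
  structure(list(kept = kept, rejected = rejected, expansions = expansions),
            class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
  cat(sprintf("CurationReport: %d kept, %d rejected, %d expanded (into %d variants)\n",
              length(x$kept), nrow(x$rejected), length(x$expansions),
              length(unlist(x$expansions))))
  invisible(x)
}

#' Write a curation report as a three-section tab-separated file
#'
#' Sections are headed \code{#kept}, \code{#rejected} (input TAB reason) and
#' \code{#expanded} (input TAB variant, one line per variant).
#'
#' @param report a \code{CurationReport}.
#' @param path output file path.
#' @export
writeCurationReport <- function(report, path) {
  stopifnot(inherits(report, "CurationReport"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#kept", con)
  writeLines(report$kept, con)
  writeLines("#rejected", con)
  if (nrow(report$rejected))
    writeLines(paste(report$rejected$input, report$rejected$reason, sep = "\t"), con)
  writeLines("#expanded", con)
  for (src in names(report$expansions))
    writeLines(paste(src, report$expansions[[src]], sep = "\t"), con)
  invisible(path)
}

#' Read a glycan corpus file
#'
#' One record per line: an IUPAC-condensed string, optionally followed by a
#' tab and a label. Blank lines and lines starting with \code{"#"} are
#' skipped. Records are returned in file order.
#'
#' @param path path to a UTF-8 text file.
#' @return data.frame with columns \code{glycan} and \code{label}
#'   (\code{NA} when absent).
#' @export
readCorpus <- function(path) {
  if (!file.exists(path))
    glycanStop("glycanIOError", "cannot read corpus file \"%s\"", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(data.frame(glycan = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    glycan = vapply(parts, `[[`, character(1), 1L),
    label = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Write a glycan corpus file
#'
#' @param glycans character vector of IUPAC-condensed strings.
#' @param path output path.
#' @param labels optional character vector of labels (tab-separated column).
#' @export
writeCorpus <- function(glycans, path, labels = NULL) {
  lines <- if (is.null(labels)) glycans else paste(glycans, labels, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
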
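#' Load a word-category lexicon in LIWC .dic dialect
#'
#' The .dic dialect is a header block of `index<TAB>category` lines
#' delimited by `%` lines, followed by body lines `word<TAB>index...`.
#' Entries ending in `*` are wildcard stems matching any token that begins
#' with the stem. The classifier feature set expects the 51-category
#' inventory, so by default a file with a different category count is
#' rejected; pass `allow_any_categories = TRUE` for toy dictionaries.
#'
#' @param path Path to a .dic file (UTF-8).
#' @param allow_any_categories Allow a category count other than 51.
#' @return A `liwc_lexicon`: list with `categories` (ordered names),
#'   `exact` (named list mapping word to integer category indices) and
#'   `stems` (list with `stem` and `cats`, sorted longest-first).
#' @export
load_dic <- function(path, allow_any_categories = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("not a .dic file: missing % header delimiters")
  header <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  header <- header[nzchar(trimws(header))]
  parts <- strsplit(header, "\t")
  idx <- as.integer(vapply(parts, `[[`, "", 1L))
  cats <- vapply(parts, `[[`, "", 2L)
  if (anyNA(idx) || any(duplicated(idx))) {
    stop("malformed .dic header: bad or duplicate category indices")
  }
  categories <- cats[order(idx)]
  lookup <- setNames(seq_along(categories), as.character(sort(idx)))
  if (!allow_any_categories && length(categories) != 51L) {
    stop(sprintf("expected 51 categories, found %d (use allow_any_categories for toy lexica)",
                 length(categories)))
  }
  body <- lines[-seq_len(pct[2])]
  body <- body[nzchar(trimws(body))]
  exact <- list()
  stems <- list(stem = character(), cats = list())
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "[\t ]+")[[1]]
    fields <- fields[nzchar(fields)]
    word <- tolower(fields[1])
    ids <- fields[-1]
    mapped <- lookup[ids]
    if (anyNA(mapped)) {
      stop(sprintf("unknown category index '%s' at body line %d",
                   paste(ids[is.na(mapped)], collapse = ","),
                   i + pct[2]))
    }
    mapped <- unname(sort(unique(mapped)))
    if (endsWith(word, "*")) {
      stems$stem <- c(stems$stem, substr(word, 1L, nchar(word) - 1L))
      stems$cats <- c(stems$cats, list(mapped))
    } else {
      exact[[word]] <- sort(unique(c(exact[[word]], mapped)))
    }
  }
  ord <- order(nchar(stems$stem), decreasing = TRUE)  # longest-match first
  structure(list(categories = categories, exact = exact,
                 stems = list(stem = stems$stem[ord],
                              cats = stems$cats[ord])),
            class = "liwc_lexicon")
}

#' @export
print.liwc_lexicon <- function(x, ...) {
  cat(sprintf("<liwc_lexicon> %d categories, %d exact entries, %d stems\n",
              length(x$categories), length(x$exact), length(x$stems$stem)))
  invisible(x)
}

#' Tokenize query text
#'
#' LIWC-convention word splitting: tokens are maximal runs of letters and
#' apostrophes (so contractions survive); everything else — digits,
#' punctuation, whitespace — separates tokens. Output is lowercased;
#' empty tokens and pure numbers never appear (numbers are not letters).
#'
#' @param text Character vector of query strings.
#' @return Character vector of lowercase tokens, in order.
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character())
  low <- tolower(text)
  toks <- unlist(regmatches(low, gregexpr("[[:alpha:]']+", low)),
                 use.names = FALSE)
  toks <- gsub("^'+|'+$", "", toks)  # strip quote apostrophes
  toks[nzchar(toks)]
}

# Category indices matched by one token: an exact entry wins outright;
# otherwise the longest matching wildcard stem applies.
match_token <- function(token, lexicon) {
  hit <- lexicon$exact[[token]]
  if (!is.null(hit)) return(hit)
  stems <- lexicon$stems$stem
  if (length(stems) > 0L) {
    ok <- startsWith(token, stems)
    if (any(ok)) return(lexicon$stems$cats[[which(ok)[1]]])  # longest first
  }
  integer()
}

#' Word-category proportions for a window
#'
#' Concatenates the window's queries in time order, tokenizes, and counts
#' how many tokens fall in each lexicon category. Values are proportions
#' of the total token count (multiply by 100 for LIWC's percentage scale);
#' a token may belong to several categories, so values need not sum to 1.
#' An empty window yields an all-zero profile.
#'
#' @param window An `observation_window` (its `queries` only; the 4-day
#'   histogram extension does not contribute).
#' @param lexicon A `liwc_lexicon`.
#' @return A `category_profile`: list with `values` (named numeric, one per
#'   category, each in \[0, 1\]) and `total_words`.
#' @export
category_profile <- function(window, lexicon) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  tokens <- tokenize(window$queries$text)
  k <- length(lexicon$categories)
  counts <- numeric(k)
  tab <- table(tokens)  # match each distinct token once
  for (i in seq_along(tab)) {
    hit <- match_token(names(tab)[i], lexicon)
    if (length(hit)) counts[hit] <- counts[hit] + tab[[i]]
  }
  total <- length(tokens)
  values <- if (total > 0L) counts / total else numeric(k)
  structure(list(values = setNames(values, lexicon$categories),
                 total_words = total),
            class = "category_profile")
}

#' Bundled fixture lexicon
#'
#' Loads the package's open 51-category fixture dictionary. Category names
#' follow the LIWC 2007 labels that matter for this analysis (anger, anx,
#' hear, percept, bio, health, sexual, sad, posemo, inhib, relativ, incl,
#' quant, preps, insight, ipron, ...) padded with standard filler
#' categories to 51. It exists so the pipeline is reproducible without the
#' proprietary LIWC dictionary; any user-supplied .dic can replace it.
#'
#' @return A `liwc_lexicon` with exactly 51 categories.
#' @export
fixture_lexicon <- function() {
  load_dic(system.file("extdata", "fixture_lexicon.dic",
                       package = "searchprint"))
}
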
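# Search-term matching in label text.
#
# Dutch writes fortificant mixtures as one word ("zinklactaat",
# "calciumcarbonaat"), so a nutrient term matches both as a standalone token
# and as the leading component of a longer compound token, optionally behind
# a chemical multiplier prefix (mono/di/tri/tetra: "tricalciumcitraat").
# Vitamin codes like B12 are matched only as standalone tokens or glued to
# "vitamine" ("vitamine-B12"); bracketed spellings such as "B(1)(2)" are
# data errors and deliberately match nothing. Matches that fall inside an
# exclusion pattern (calcium-D-pantothenate is pantothenic acid, not a
# calcium fortificant) are removed.

# normalise a spec argument: one row of the nutrient_specs() tibble, or a
# list with the same fields
as_nutrient_spec <- function(spec) {
  if (is.data.frame(spec)) {
    if (nrow(spec) != 1) abort("`spec` must be a single nutrient (one row)")
    spec <- as.list(spec)
    spec$specific_terms <- spec$specific_terms[[1]]
    spec$exclusion_patterns <- spec$exclusion_patterns[[1]]
  }
  spec
}

.empty_matches <- function() {
  tibble(
    term = character(), start = integer(), end = integer(),
    token_first = integer(), token_last = integer(),
    in_additive_context = logical(),
    in_natural_content_remark = logical(),
    in_fortification_remark = logical()
  )
}

# single-token term match against all tokens; returns indices
.match_single_term <- function(tokens, term, prefixes) {
  if (grepl("^b[0-9]+$", term)) {
    return(which(tokens == term |
                   tokens == paste0("vitamine-", term) |
                   tokens == paste0("vitamine", term)))
  }
  hit <- startsWith(tokens, term)
  for (p in prefixes) hit <- hit | startsWith(tokens, paste0(p, term))
  which(hit)
}

# all raw matches of the term list inside a tokenised text
.match_terms <- function(tok, terms, prefixes) {
  out <- vector("list", length(terms))
  for (ti in seq_along(terms)) {
    term <- terms[ti]
    parts <- strsplit(term, " +")[[1]]
    if (length(parts) == 1) {
      idx <- .match_single_term(tok$token, term, prefixes)
      if (length(idx)) out[[ti]] <- cbind(first = idx, last = idx, term = ti)
    } else {
      n <- length(tok$token)
      k <- length(parts)
      if (n < k) next
      hit <- startsWith(tok$token, parts[1]) | tok$token == parts[1]
      for (p in prefixes) hit <- hit | startsWith(tok$token, paste0(p, parts[1]))
      first <- which(hit)
      first <- first[first + k - 1 <= n]
      keep <- vapply(first, function(i) {
        mid_ok <- all(tok$token[i + seq_len(k - 2)] == parts[2:(k - 1)]) ||
          k == 2
        mid_ok && startsWith(tok$token[i + k - 1], parts[k])
      }, logical(1))
      first <- first[keep]
      if (length(first)) out[[ti]] <- cbind(first = first, last = first + k - 1L, term = ti)
    }
  }
  m <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(m)) m <- cbind(first = integer(0), last = integer(0), term = integer(0))
  m
}

# drop matches covered by a longer match on an overlapping token range;
# ties on span go to the longest lexicon term
.dedup_matches <- function(m, tok, term_len = NULL) {
  if (nrow(m) <= 1) return(m)
  span <- tok$end[m[, "last"]] - tok$start[m[, "first"]]
  tl <- if (is.null(term_len)) rep(0L, nrow(m)) else term_len[m[, "term"]]
  ord <- order(-span, -tl, m[, "first"])
  m <- m[ord, , drop = FALSE]
  span <- span[ord]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    if (i < nrow(m)) {
      for (j in (i + 1):nrow(m)) {
        if (keep[j] && m[j, "first"] <= m[i, "last"] && m[j, "last"] >= m[i, "first"]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  m[keep, , drop = FALSE]
}

# token indices where an additive class name ends
.additive_anchor_tokens <- function(tok, lexicon) {
  classes <- c(lexicon$additive_classes$dutch, lexicon$additive_class_variants)
  anchors <- integer(0)
  for (cl in classes) {
    parts <- strsplit(cl, " +")[[1]]
    if (length(parts) == 1) {
      anchors <- c(anchors, which(tok$token == cl))
    } else {
      mm <- match_token_phrase(tok, parts)
      anchors <- c(anchors, mm[, "last"])
    }
  }
  sort(unique(anchors))
}

.in_additive_context <- function(tok, token_first, anchors, window) {
  if (length(anchors) == 0) return(FALSE)
  # (a) inside a bracket/colon group opened at a class name
  if (any(tok$openers[[token_first]] %in% anchors)) return(TRUE)
  # (b) class name within `window` tokens immediately before the match,
  #     with no ingredient separator in between
  prev <- anchors[anchors < token_first & anchors >= token_first - window]
  for (g in prev) {
    if (!any(tok$hard_before[(g + 1):token_first])) return(TRUE)
  }
  FALSE
}

# phrase-end token indices for a list of phrases
.phrase_ends <- function(tok, phrases) {
  ends <- integer(0)
  for (ph in phrases) {
    parts <- strsplit(ph, " +")[[1]]
    if (length(parts) == 1) {
      ends <- c(ends, which(tok$token == ph))
    } else {
      mm <- match_token_phrase(tok, parts)
      ends <- c(ends, mm[, "last"])
    }
  }
  sort(unique(ends))
}

.remark_flags <- function(token_first, natural_ends, fort_ends, window) {
  c(
    natural = any(natural_ends < token_first &
                    natural_ends >= token_first - window),
    fortification = any(fort_ends < token_first &
                          fort_ends >= token_first - window)
  )
}

# decorate integer match positions with spans and context flags
.matches_tibble <- function(m, term_names, tok, lexicon) {
  if (nrow(m) == 0) return(.empty_matches())
  anchors <- .additive_anchor_tokens(tok, lexicon)
  nat_ends <- .phrase_ends(tok, lexicon$natural_content_phrases)
  fort_ends <- .phrase_ends(tok, lexicon$fortification_phrases)
  flags <- t(vapply(m[, "first"], .remark_flags, c(natural = TRUE, fortification = TRUE),
                    natural_ends = nat_ends, fort_ends = fort_ends,
                    window = lexicon$remark_window))
  tibble(
    term = term_names[m[, "term"]],
    start = tok$start[m[, "first"]],
    end = tok$end[m[, "last"]],
    token_first = as.integer(m[, "first"]),
    token_last = as.integer(m[, "last"]),
    in_additive_context = vapply(m[, "first"], .in_additive_context, logical(1),
                                 tok = tok, anchors = anchors,
                                 window = lexicon$additive_window),
    in_natural_content_remark = unname(flags[, "natural"]),
    in_fortification_remark = unname(flags[, "fortification"])
  )
}

# shared workers over a pre-tokenised text
.find_specific_tok <- function(tok, spec, lexicon) {
  if (is.null(tok)) return(.empty_matches())
  .matches_tibble(.match_positions(tok, spec, lexicon), spec$specific_terms,
                  tok, lexicon)
}

.find_generic_tok <- function(tok, lexicon, qualifier_set) {
  if (is.null(tok)) return(.empty_matches())
  .matches_tibble(.generic_positions(tok, lexicon, qualifier_set),
                  lexicon$generic_terms, tok, lexicon)
}

.is_qualifier <- function(token, qualifier_set) {
  if (token %in% qualifier_set$exact) return(TRUE)
  any(startsWith(token, qualifier_set$leading))
}

# qualifier set = configured names + every specific term of every nutrient
.build_qualifier_set <- function(lexicon, specs) {
  all_terms <- unique(unlist(specs$specific_terms))
  first_words <- vapply(strsplit(all_terms, " +"), `[`, "", 1)
  list(
    exact = unique(c(lexicon$qualifier_terms, all_terms)),
    leading = unique(first_words[nchar(first_words) >= 4])
  )
}

#' Find nutrient-specific search terms in label text
#'
#' Case-insensitive matching of a nutrient's Dutch search terms, as
#' standalone tokens or as the leading component of compound tokens
#' (optionally behind a mono/di/tri/tetra prefix). Matches inside an
#' exclusion pattern are removed; overlapping matches collapse onto the
#' longest term. Every surviving match carries context flags: whether it is
#' governed by a food-additive class name, and whether a natural-content or
#' fortification phrase precedes it.
#'
#' @param text A single character string (the ingredient list or another
#'   label field). `NA` and `""` yield zero matches.
#' @param spec One nutrient's specification: a single row of
#'   [nutrient_specs()].
#' @param lexicon A [default_lexicon()] object.
#' @return A tibble with one row per match: `term`, `start`, `end` (0-based
#'   half-open offsets into the normalised text), `token_first`,
#'   `token_last`, `in_additive_context`, `in_natural_content_remark`,
#'   `in_fortification_remark`.
#' @examples
#' spec <- dplyr::filter(nutrient_specs(), nutrient_id == "zinc")
#' find_specific_terms("water, zinklactaat, aroma", spec, default_lexicon())
#' @export
find_specific_terms <- function(text, spec, lexicon = default_lexicon()) {
  spec <- as_nutrient_spec(spec)
  .find_specific_tok(tokenize_label(text), spec, lexicon)
}

#' Find generic vitamin/mineral wordings in label text
#'
#' Matches generic wordings such as "vitaminen en mineralen" only when they
#' are not immediately qualified by a specific micronutrient name:
#' "vitamine C" is a specific vitamin, bare "vitaminen en mineralen" is
#' generic. The qualification check uses the union of all configured
#' nutrient search terms and a built-in list of other vitamin and mineral
#' names.
#'
#' @inheritParams find_specific_terms
#' @param specs The full nutrient specification table, used for the
#'   qualification check.
#' @return A tibble in the same shape as [find_specific_terms()].
#' @examples
#' find_generic_terms("met toegevoegde vitaminen en mineralen",
#'                    default_lexicon(), nutrient_specs())
#' @export
find_generic_terms <- function(text, lexicon = default_lexicon(),
                               specs = nutrient_specs()) {
  qs <- .build_qualifier_set(lexicon, specs)
  .find_generic_tok(tokenize_label(text), lexicon, qs)
}

#' Is a match governed by a food-additive class name?
#'
#' True when a functional ingredient class name (stabiliser, antioxidant,
#' thickener, ...) governs the matched term: the class opens the bracketed
#' or colon-delimited group the match sits in ("verdikkingsmiddel
#' (calciumalginaat)"), or it stands at most `additive_window` tokens before
#' the match with no ingredient separator in between. A nutrient in additive
#' context is a processing aid, not a fortificant.
#'
#' @param text The searched text.
#' @param match One row of a match tibble from [find_specific_terms()], or a
#'   0-based character offset of the match start.
#' @param lexicon A [default_lexicon()] object.
#' @return Logical scalar.
#' @examples
#' spec <- dplyr::filter(nutrient_specs(), nutrient_id == "calcium")
#' m <- find_specific_terms("verdikkingsmiddel (calciumalginaat)", spec)
#' detect_additive_context("verdikkingsmiddel (calciumalginaat)", m[1, ])
#' @export
detect_additive_context <- function(text, match, lexicon = default_lexicon()) {
  tok <- tokenize_label(text)
  if (is.null(tok)) return(FALSE)
  j <- .match_token_index(tok, match)
  anchors <- .additive_anchor_tokens(tok, lexicon)
  .in_additive_context(tok, j, anchors, lexicon$additive_window)
}

#' Natural-content and fortification phrasing around a match
#'
#' Checks whether a phrase meaning "source of / rich in" (natural content)
#' or "added / fortified with" ends within `remark_window` tokens before the
#' match.
#'
#' @inheritParams detect_additive_context
#' @return A named logical vector with elements `in_natural_content_remark`
#'   and `in_fortification_remark`.
#' @examples
#' spec <- dplyr::filter(nutrient_specs(), nutrient_id == "calcium")
#' m <- find_specific_terms("rijk aan calcium", spec)
#' detect_remarks("rijk aan calcium", m[1, ])
#' @export
detect_remarks <- function(text, match, lexicon = default_lexicon()) {
  tok <- tokenize_label(text)
  empty <- c(in_natural_content_remark = FALSE, in_fortification_remark = FALSE)
  if (is.null(tok)) return(empty)
  j <- .match_token_index(tok, match)
  fl <- .remark_flags(j,
                      .phrase_ends(tok, lexicon$natural_content_phrases),
                      .phrase_ends(tok, lexicon$fortification_phrases),
                      lexicon$remark_window)
  c(in_natural_content_remark = unname(fl["natural"]),
    in_fortification_remark = unname(fl["fortification"]))
}

.match_token_index <- function(tok, match) {
  if (is.data.frame(match)) {
    if ("token_first" %in% names(match)) return(match$token_first[[1]])
    off <- match$start[[1]]
  } else {
    off <- match[[1]]
  }
  j <- which(tok$start <= off & tok$end > off)
  if (length(j) == 0) abort("`match` offset lies outside the tokenised text")
  j[1]
}
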
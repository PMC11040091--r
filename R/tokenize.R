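# Label-text normalisation and tokenisation.
#
# Dutch ingredient lists separate ingredients with commas and semicolons and
# group sub-ingredients with brackets or a colon after the governing word
# ("stabilisator: calciumcarbonaat"). Tokens are split on those separators
# plus slashes and whitespace; hyphens and periods stay inside tokens, which
# keeps chemical spellings like "calcium-D-pantothenaat" and vitamin codes
# like "B12" intact. A bracketed spelling such as "B(1)(2)" therefore falls
# apart into tokens that match nothing, which is the intended treatment of
# that data error.

#' Normalise label text
#'
#' Lower-cases and strips diacritics. All matching in the package operates
#' on text normalised this way, making every match case-insensitive.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
normalize_label_text <- function(x) {
  if (length(x) == 0) return(character())
  tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

.token_regex <- "[^,;:()\\[\\]{}/\\\\[:space:]]+"

# Tokenise one label text. Returns NULL for NA/empty input, otherwise a list:
#   norm        normalised text
#   token       character vector of tokens
#   start, end  0-based half-open character offsets into `norm`
#   hard_before TRUE when a comma/semicolon separates this token from the
#               previous one (an ingredient boundary)
#   openers     per token, integer vector of token indices that open the
#               bracket/colon groups enclosing it (innermost last)
tokenize_label <- function(text) {
  if (length(text) != 1 || is.na(text)) return(NULL)
  norm <- normalize_label_text(text)
  loc <- stringi::stri_locate_all_regex(norm, .token_regex)[[1]]
  if (nrow(loc) == 0 || is.na(loc[1, 1])) return(NULL)
  starts <- loc[, 1]
  ends <- loc[, 2]
  n <- length(starts)
  token <- stringi::stri_sub(norm, starts, ends)

  gaps <- character(n)
  gaps[1] <- if (starts[1] > 1) substr(norm, 1, starts[1] - 1) else ""
  if (n > 1) {
    gaps[2:n] <- substr(rep(norm, n - 1), ends[1:(n - 1)] + 1, starts[2:n] - 1)
  }
  hard_before <- stringr::str_detect(gaps, "[,;]")

  # bracket groups: map each open bracket to the token right before it
  chars <- strsplit(norm, "")[[1]]
  open_pos <- which(chars %in% c("(", "[", "{"))
  close_pos <- which(chars %in% c(")", "]", "}"))
  events <- rbind(
    if (length(open_pos)) cbind(open_pos, 1L),
    if (length(close_pos)) cbind(close_pos, 2L),
    cbind(starts, 3L)
  )
  events <- events[order(events[, 1], events[, 2]), , drop = FALSE]
  stack <- integer(0)
  bracket_openers <- vector("list", n)
  tok_i <- 0L
  for (r in seq_len(nrow(events))) {
    pos <- events[r, 1]
    type <- events[r, 2]
    if (type == 1L) {
      # opener token: last token ending before the bracket, with no
      # ingredient separator between it and the bracket
      before <- which(ends < pos)
      op <- NA_integer_
      if (length(before) > 0) {
        cand <- max(before)
        between <- substr(norm, ends[cand] + 1, pos - 1)
        if (!stringr::str_detect(between, "[,;]")) op <- cand
      }
      stack <- c(stack, op)
    } else if (type == 2L) {
      if (length(stack) > 0) stack <- stack[-length(stack)]
    } else {
      tok_i <- tok_i + 1L
      bracket_openers[[tok_i]] <- stack[!is.na(stack)]
    }
  }

  # colon groups: "stabilisator: calciumcarbonaat, zout" puts the tokens up
  # to the next ingredient separator under the governing token
  openers <- bracket_openers
  colon_opener <- NA_integer_
  for (i in seq_len(n)) {
    g <- gaps[i]
    if (stringr::str_detect(g, "[,;\\)\\]}]")) colon_opener <- NA_integer_
    if (stringr::str_detect(g, ":")) {
      # a hard separator after the colon (":a," handled above) cancels it
      last_colon <- max(stringi::stri_locate_all_fixed(g, ":")[[1]][, 1])
      hard_in_g <- stringi::stri_locate_all_regex(g, "[,;\\)\\]}]")[[1]][, 1]
      if (length(hard_in_g) == 0 || all(is.na(hard_in_g)) ||
          max(hard_in_g, na.rm = TRUE) < last_colon) {
        colon_opener <- if (i > 1) i - 1L else NA_integer_
      }
    }
    if (!is.na(colon_opener) && colon_opener < i) {
      openers[[i]] <- unique(c(openers[[i]], colon_opener))
    }
  }

  list(
    norm = norm, token = token,
    start = as.integer(starts - 1L), end = as.integer(ends),
    hard_before = hard_before, openers = openers
  )
}

# Find occurrences of a multi-token phrase (exact token equality).
# Returns integer matrix with columns first, last (token indices).
match_token_phrase <- function(tok, phrase_tokens) {
  k <- length(phrase_tokens)
  n <- length(tok$token)
  if (k == 0 || n < k) return(cbind(first = integer(0), last = integer(0)))
  hit <- tok$token == phrase_tokens[1]
  if (k > 1) {
    for (j in 2:k) {
      hit <- hit & c(tok$token[-seq_len(j - 1)] == phrase_tokens[j],
                     rep(FALSE, j - 1))
    }
  }
  first <- which(hit)
  cbind(first = first, last = first + k - 1L)
}
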
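# Independent brute-force re-implementation of the decision tree as a
# literal nested conditional, with its own string matching (iconv + regex
# over comma-delimited items rather than the package's offset tokenizer).
# Used only as a cross-check against classify_foods().

oracle_terms <- list(
  calcium = c("calcium", "calciumcarbonaat", "calciumfosfaat",
              "dicalciumfosfaat", "calciumlactaat", "tricalciumcitraat",
              "calciumcitraat", "calciumzouten van orthofosforzuur",
              "dicalciumdicitraat", "calciumhydroxide"),
  folic_acid = c("foliumzuur", "b9", "b11", "folaat", "tetrahydrofolaat",
                 "polyglytamaat", "pfteroylmonoglutaminezuur", "folic acid",
                 "folinezuur", "foliumzout"),
  vitamin_b12 = c("b12", "cobalamine", "cyanocobalamine"),
  zinc = c("zink", "zinklactaat", "zink lactaat", "zinksulfaat",
           "zink sulfaat", "zinkoxide", "zink oxide", "zinkgluconaat",
           "zink gluconaat", "zinkcitraat", "zink citraat")
)
oracle_dri <- c(calcium = 800, folic_acid = 200, vitamin_b12 = 2.5, zinc = 10)
oracle_additive_classes <- c(
  "zuur", "zuurteregelaar", "antiklontermiddel", "antischuimmiddel",
  "antioxidant", "vulstof", "kleurstof", "emulgator", "smeltzouten",
  "verstevigingsmiddel", "smaakversterker", "meelverbeteraar",
  "schuimmiddel", "geleermiddel", "glansmiddel", "bevochtigingsmiddel",
  "gemodificeerd zetmeel", "conserveermiddel", "drijfgas", "rijsmiddel",
  "complexvormer", "stabilisator", "zoetstof", "verdikkingsmiddel",
  "stabilisatoren", "emulgatoren", "kleurstoffen", "conserveermiddelen",
  "conserveringsmiddel", "conserveringsmiddelen", "verdikkingsmiddelen",
  "zuurteregelaars", "antioxidanten", "rijsmiddelen", "geleermiddelen",
  "zoetstoffen", "smaakversterkers", "voedingszuur"
)
oracle_ineligible <- tolower(c(
  "Foods and formulae for infants and young children",
  "Foods for specific medical purposes",
  "Total diet replacement for weight control", "Food supplements"
))
oracle_bev_subs <- c("milk", "chocolate milk", "condensed milk",
                     "coffee milk/cream", "buttermilk", "dairy drinks",
                     "liquid breakfast")
oracle_generic <- c("vitamine", "vitaminen", "vitamines", "mineralen",
                    "mineraal")
oracle_qualifiers <- c(
  "a", "b", "c", "d", "e", "k", "b1", "b2", "b3", "b5", "b6", "b7", "b8",
  "b12", "d2", "d3", "k1", "k2", "ijzer", "jodium", "selenium", "koper",
  "magnesium", "kalium", "fosfor", "mangaan", "chroom", "molybdeen",
  "fluoride", "chloride", "natrium", "biotine", "niacine", "thiamine",
  "riboflavine", "pantotheenzuur", "ascorbinezuur", "retinol",
  "cholecalciferol", "tocoferol"
)
oracle_all_terms <- unique(unlist(oracle_terms))

o_norm <- function(x) {
  tolower(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
}

# split a text into comma/semicolon-delimited items; each item into tokens
o_items <- function(text) {
  items <- strsplit(o_norm(text), "[,;]")[[1]]
  lapply(items, function(it) {
    tk <- strsplit(it, "[]()[{}/:\\\\[:space:]]+")[[1]]
    tk[nzchar(tk)]
  })
}

o_token_matches_term <- function(token, term) {
  if (grepl("^b[0-9]+$", term)) {
    return(token == term || token == paste0("vitamine-", term) ||
             token == paste0("vitamine", term))
  }
  grepl(paste0("^(mono|di|tri|tetra)?", term), token)
}

# positions (item, token) where a nutrient term starts, after exclusions
o_find_term_positions <- function(items, nutrient) {
  terms <- oracle_terms[[nutrient]]
  hits <- list()
  for (ii in seq_along(items)) {
    tk <- items[[ii]]
    for (jj in seq_along(tk)) {
      if (nutrient == "calcium" && grepl("calcium-d-pantothena", tk[jj])) next
      matched <- FALSE
      for (term in terms) {
        tparts <- strsplit(term, " ")[[1]]
        if (length(tparts) == 1) {
          if (o_token_matches_term(tk[jj], term)) matched <- TRUE
        } else {
          if (jj + length(tparts) - 1 <= length(tk)) {
            seg <- tk[jj:(jj + length(tparts) - 1)]
            ok <- o_token_matches_term(seg[1], tparts[1])
            for (q in seq_along(tparts)[-1]) {
              ok <- ok && grepl(paste0("^", tparts[q]), seg[q])
            }
            if (ok) matched <- TRUE
          }
        }
        if (matched) break
      }
      if (matched) hits <- c(hits, list(c(ii, jj)))
    }
  }
  hits
}

# is the term at (item, token) governed by an additive class name? the
# class must sit earlier in the same comma-delimited item, within 3 tokens
o_additive <- function(items, pos) {
  tk <- items[[pos[1]]]
  j <- pos[2]
  lo <- max(1, j - 3)
  if (j == 1) return(FALSE)
  any(tk[lo:(j - 1)] %in% oracle_additive_classes)
}

o_natural_remark <- function(items, pos) {
  tk <- items[[pos[1]]]
  j <- pos[2]
  before <- tk[max(1, j - 3):max(1, j - 1)]
  s <- paste(before, collapse = " ")
  j > 1 && (grepl("rijk aan", s) || grepl("bron van", s))
}

o_fort_remark <- function(items, pos) {
  tk <- items[[pos[1]]]
  j <- pos[2]
  before <- tk[max(1, j - 3):max(1, j - 1)]
  j > 1 && any(grepl("^(verrijkt|toegevoegd|toegevoegde|toevoeging)$", before))
}

o_has_generic <- function(items) {
  for (ii in seq_along(items)) {
    tk <- items[[ii]]
    for (jj in seq_along(tk)) {
      if (tk[jj] %in% oracle_generic) {
        nxt <- if (jj < length(tk)) tk[jj + 1] else NA_character_
        if (tk[jj] %in% c("vitamine", "vitaminen", "vitamines") &&
            !is.na(nxt) && nxt == "en") {
          nxt <- if (jj + 2 <= length(tk)) tk[jj + 2] else NA_character_
          nxt <- if (!is.na(nxt) && nxt %in% c("mineralen", "mineraal")) {
            if (jj + 3 <= length(tk)) tk[jj + 3] else NA_character_
          } else nxt
        }
        qualified <- !is.na(nxt) &&
          (nxt %in% oracle_qualifiers || nxt %in% oracle_all_terms ||
             any(vapply(oracle_all_terms[nchar(oracle_all_terms) >= 4],
                        function(tt) startsWith(nxt, strsplit(tt, " ")[[1]][1]),
                        logical(1))))
        if (!qualified) return(TRUE)
      }
    }
  }
  FALSE
}

# step 7 on one claim field
o_claim <- function(text, nutrient) {
  if (is.na(text) || !nzchar(text)) return(c(fort = FALSE, natural = FALSE))
  items <- o_items(text)
  fort <- natural <- FALSE
  for (pos in o_find_term_positions(items, nutrient)) {
    if (o_fort_remark(items, pos)) fort <- TRUE
    if (o_natural_remark(items, pos)) natural <- TRUE
  }
  # generic wording under the same remark rules
  for (ii in seq_along(items)) {
    tk <- items[[ii]]
    for (jj in seq_along(tk)) {
      if (tk[jj] %in% oracle_generic) {
        nxt <- if (jj < length(tk)) tk[jj + 1] else NA_character_
        qualified <- !is.na(nxt) &&
          (nxt %in% oracle_qualifiers || nxt %in% oracle_all_terms ||
             any(vapply(oracle_all_terms[nchar(oracle_all_terms) >= 4],
                        function(tt) startsWith(nxt, strsplit(tt, " ")[[1]][1]),
                        logical(1))))
        if (qualified) next
        if (o_fort_remark(items, c(ii, jj))) fort <- TRUE
        if (o_natural_remark(items, c(ii, jj))) natural <- TRUE
      }
    }
  }
  c(fort = fort, natural = natural)
}

# the decision tree as one literal nested conditional
oracle_classify_one <- function(rec, nutrient) {
  grp <- rec$food_group
  if (is.na(grp) || !nzchar(trimws(grp)) ||
      tolower(grp) %in% oracle_ineligible) {
    return("ineligible")
  }

  step7 <- function() {
    cl <- o_claim(rec$legal_name, nutrient)
    cm <- o_claim(rec$mandatory_particulars, nutrient)
    if (cl["fort"] || cm["fort"]) return("fortified")
    "non_fortified"
  }

  value <- if (nutrient == "folic_acid") {
    if (!is.na(rec$dfe)) rec$dfe else rec$folic_acid
  } else {
    rec[[nutrient]]
  }
  if (is.na(value)) return(step7())

  bev <- tolower(grp) == "drinks" ||
    (!is.na(rec$food_subgroup) && tolower(rec$food_subgroup) %in% oracle_bev_subs)
  threshold <- oracle_dri[[nutrient]] * (if (bev) 0.075 else 0.15)
  if (value < threshold) return(step7())

  ing <- rec$ingredient_list
  items <- if (is.na(ing) || !nzchar(ing)) list() else o_items(ing)
  positions <- if (length(items)) o_find_term_positions(items, nutrient) else list()

  if (length(positions) == 0) {
    if (length(items) && o_has_generic(items)) return("fortified")
    return(step7())
  }

  additive <- vapply(positions, function(p) o_additive(items, p), logical(1))
  natural <- vapply(positions, function(p) o_natural_remark(items, p), logical(1))
  if (all(additive)) return(step7())
  if (any(!additive & !natural)) return("fortified")
  "non_fortified"
}

oracle_classify <- function(records, nutrients = names(oracle_terms)) {
  records <- as.data.frame(records)
  labs <- matrix(NA_character_, nrow(records), length(nutrients))
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    for (k in seq_along(nutrients)) {
      labs[r, k] <- oracle_classify_one(rec, nutrients[k])
    }
  }
  data.frame(
    food_id = rep(records$food_id, each = length(nutrients)),
    nutrient = rep(nutrients, times = nrow(records)),
    label = as.vector(t(labs)),
    stringsAsFactors = FALSE
  )
}
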
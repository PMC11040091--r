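# Small record builders shared across test files.

make_record <- function(food_id = "f1", food_group = "Bread",
                        food_subgroup = NA_character_,
                        food_name = "testproduct",
                        ingredient_list = NA_character_,
                        legal_name = NA_character_,
                        mandatory_particulars = NA_character_,
                        calcium = NA_real_, folic_acid = NA_real_,
                        dfe = NA_real_, vitamin_b12 = NA_real_,
                        zinc = NA_real_, single_portion = FALSE) {
  tibble::tibble(
    food_id = food_id, food_group = food_group,
    food_subgroup = food_subgroup, food_name = food_name,
    ingredient_list = ingredient_list, legal_name = legal_name,
    mandatory_particulars = mandatory_particulars,
    calcium = calcium, folic_acid = folic_acid, dfe = dfe,
    vitamin_b12 = vitamin_b12, zinc = zinc, single_portion = single_portion
  )
}

spec_for <- function(nutrient, specs = nutrient_specs()) {
  specs[specs$nutrient_id == nutrient, ]
}

label_of <- function(results, id, nutrient) {
  as.character(results$label[results$food_id == id &
                               results$nutrient == nutrient])
}

# flip the case of random characters, reproducibly
flip_case <- function(text, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(text, "")[[1]]
    i <- runif(length(ch)) < 0.5
    ch[i] <- toupper(ch[i])
    paste(ch, collapse = "")
  })
}

# exact P(all |N_i - n_i| <= c) for a 3-category multinomial with
# p = counts / n, by full enumeration (test oracle for the Sison-Glaz
# coverage approximation)
exact_nu <- function(cc, counts) {
  n <- sum(counts)
  p <- counts / n
  tot <- 0
  for (a in max(0, counts[1] - cc):min(n, counts[1] + cc)) {
    for (b in max(0, counts[2] - cc):min(n - a, counts[2] + cc)) {
      d <- n - a - b
      if (d >= 0 && abs(d - counts[3]) <= cc) {
        tot <- tot + stats::dmultinom(c(a, b, d), prob = p)
      }
    }
  }
  tot
}
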
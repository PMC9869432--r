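# shared helpers for building small fixtures in code

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","K","L","M","F","P","S",
          "T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# uniformly random synonymous coding sequence for a protein
code_for <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), as.character(gc))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) sample(by_aa[[a]], 1L), character(1)),
        collapse = "")
}

# sum of diagonal substitution scores for a protein against itself
diag_score <- function(protein, params = scoring_params()) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  sum(params$matrix[cbind(aa, aa)])
}
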
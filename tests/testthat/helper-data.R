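# In-code fixture builders shared across test files.

toy_dataset <- function(values, donor = "D1", regions = NULL,
                        condition = NULL, age = NULL, ranked = FALSE) {
  meta <- data.frame(sample_id = colnames(values), donor_id = donor,
                     stringsAsFactors = FALSE)
  if (!is.null(regions)) meta$region <- regions
  if (!is.null(condition)) meta$condition <- condition
  if (!is.null(age)) meta$age_years <- age
  expression_dataset(values, meta, ranked = ranked)
}

# A one-donor regional dataset where the seed row and set rows are chosen
# explicitly; remaining genes are deterministic filler.
toy_regional <- function(seed_row, other_rows, donor = "D1", age = NULL) {
  vals <- rbind(SEED = seed_row, other_rows)
  colnames(vals) <- sprintf("%s_R%02d", donor, seq_len(ncol(vals)))
  toy_dataset(vals, donor = donor,
              regions = sprintf("R%02d", seq_len(ncol(vals))), age = age,
              ranked = TRUE)
}

planted_set <- function(n = 73) gene_set("planted", sprintf("SETG%03d", 1:n))
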
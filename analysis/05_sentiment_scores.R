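#!/usr/bin/env Rscript
# Stage 5: lexicon sentiment scoring, dimension aggregation, cue coverage.
#
# Scores every labeled clause with the rule-based algorithm (degree adverbs
# multiply, an odd number of negation words in scope flips the sign),
# aggregates to doctor-week dimension scores normalized by token counts,
# and computes the coverage statistics: the share of reviews and doctors
# mentioning each dimension and the distribution of distinct dimensions
# per review / doctor.

suppressPackageStartupMessages({
  library(readr)
  library(jsonlite)
  library(hsq5d)
})

clauses <- read_clauses("results/data/clauses_labeled.csv")
lex <- read_lexicons("results/data/lexicon_polarity.tsv",
                     "results/data/lexicon_degree.tsv",
                     "results/data/lexicon_negation.tsv")

scored <- score_clauses(clauses, lex)
dim_scores <- aggregate_dimension_scores(scored)
write_csv(dim_scores, "results/dimension_scores.csv")

cat(sprintf("Scored %d clauses; %d doctor-week-dimension rows.\n",
            nrow(scored), nrow(dim_scores)))
cat("Mean dimension scores (patients' perceived quality):\n")
print(round(tapply(dim_scores$score, dim_scores$dimension, mean)[DIMENSIONS], 4))

cov <- cue_coverage(clauses)
write_csv(cov$review_dimension, "results/coverage_review_dimension.csv")
write_csv(cov$doctor_dimension, "results/coverage_doctor_dimension.csv")
write_csv(cov$review_k, "results/coverage_review_k.csv")
write_csv(cov$doctor_k, "results/coverage_doctor_k.csv")

cat("\nShare of reviews mentioning each dimension (%):\n")
print(setNames(cov$review_dimension$share_pct, cov$review_dimension$dimension))
with(cov, cat(sprintf(
  "\nReviews with >= 1 cue: %.2f%% (%d/%d); doctors with all 5 cues: %.2f%% (%d/%d)\n",
  review_k$share_at_least_pct[review_k$k == 1], review_k$n_at_least[review_k$k == 1],
  n_reviews,
  doctor_k$share_exactly_pct[doctor_k$k == 5], doctor_k$n_exactly[doctor_k$k == 5],
  n_doctors
)))

# agreement with the generator's truth-label scores
truth <- read_csv("results/data/truth_dimension_scores.csv", show_col_types = FALSE)
merged <- merge(dim_scores, truth, by = c("doctor_id", "week", "dimension"))
cat(sprintf("Correlation with truth-label dimension scores: %.4f (%d rows)\n",
            cor(merged$score.x, merged$score.y), nrow(merged)))
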
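# Small in-code fixtures shared across test files.

toy_tree <- function() as_speciational(read_newick("((A,B),(C,D));"))

# A 23-tip speciational stand-in tree, the package's reference clade size.
study_tree <- function(seed = 101) gen_yule_tree(23, seed = seed)

toy_tips <- function() {
  tip_phenotypes(c("A", "B", "C", "D", "E"),
                 male = c(1.2, -0.3, 0.8, 2.1, -1.0),
                 female = c(0.7, -0.9, 0.1, 1.5, -1.4))
}

# Build a null_distribution by hand (for closed-form discrimination checks).
fake_null <- function(values, model = "constraint_on_females",
                      statistic = "DSD") {
  ci <- ci95(values)
  structure(list(model = model, statistic = statistic, values = values,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "null_distribution")
}
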
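# Published census-weighted same-trait correlations for the 21 pairs of the
# seven samples, with the published design-class labels, used as input data
# for Fisher-pooling checks. Column order: Conscientiousness, Agreeableness,
# Neuroticism, Openness, Extraversion.
published_pair_panel <- function() {
  raw <- rbind(
    c("Sample1",  "Sample2",  "S", "S", "A", 0.72, 0.76, 0.80, 0.85, 0.70),
    c("SAPA2010", "SAPA2015", "S", "S", "A", 0.41, 0.47, 0.64, 0.63, 0.65),
    c("Sample3",  "Sample5",  "S", "D", "S", 0.23, 0.05, 0.47, 0.34, -0.20),
    c("Sample2",  "Sample3",  "D", "D", "S", 0.45, 0.49, 0.66, 0.62, 0.59),
    c("Sample2",  "Sample4",  "D", "D", "S", 0.61, 0.28, 0.67, 0.85, 0.21),
    c("Sample2",  "Sample5",  "D", "D", "S", 0.31, 0.31, 0.45, 0.68, -0.11),
    c("Sample3",  "Sample4",  "D", "D", "S", 0.14, 0.37, 0.64, 0.67, 0.12),
    c("Sample4",  "Sample5",  "D", "D", "S", 0.27, 0.19, 0.63, 0.65, 0.46),
    c("Sample2",  "SAPA2010", "D", "D", "S", 0.27, 0.19, 0.41, 0.48, 0.20),
    c("Sample3",  "SAPA2010", "D", "D", "S", 0.12, 0.15, 0.48, 0.19, 0.36),
    c("Sample4",  "SAPA2010", "D", "D", "S", 0.21, -0.16, 0.53, 0.29, 0.35),
    c("Sample5",  "SAPA2010", "D", "D", "S", 0.11, -0.23, 0.40, 0.27, 0.17),
    c("Sample1",  "Sample3",  "D", "D", "A", 0.37, 0.53, 0.77, 0.70, 0.56),
    c("Sample1",  "Sample4",  "D", "D", "A", 0.70, 0.62, 0.74, 0.72, 0.20),
    c("Sample1",  "Sample5",  "D", "D", "A", 0.30, 0.26, 0.54, 0.53, -0.06),
    c("Sample1",  "SAPA2010", "D", "D", "A", 0.26, -0.02, 0.53, 0.43, 0.27),
    c("Sample2",  "SAPA2015", "D", "D", "A", 0.47, 0.41, 0.66, 0.36, 0.25),
    c("Sample3",  "SAPA2015", "D", "D", "A", 0.37, 0.22, 0.59, 0.09, 0.21),
    c("Sample4",  "SAPA2015", "D", "D", "A", 0.41, -0.16, 0.72, 0.18, 0.37),
    c("Sample5",  "SAPA2015", "D", "D", "A", 0.43, 0.11, 0.49, 0.22, 0.09),
    c("Sample1",  "SAPA2015", "D", "D", "N", 0.37, 0.11, 0.76, 0.43, 0.28)
  )
  traits <- c("Conscientiousness", "Agreeableness", "Neuroticism",
              "Openness", "Extraversion")
  out <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    data.frame(
      sample_a = raw[i, 1], sample_b = raw[i, 2],
      inv = raw[i, 3], proj = raw[i, 4], time = raw[i, 5],
      trait = traits, r = as.numeric(raw[i, 6:10]),
      n_units = 49L, stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("convergence_panel", "data.frame")
  out
}

# Summary metadata for the seven samples (inventory, project, period)
published_sample_meta <- function() {
  data.frame(
    sample_id = c("Sample1", "Sample2", "Sample3", "Sample4", "Sample5",
                  "SAPA2010", "SAPA2015"),
    inventory = c("BFI", "BFI", "TIPI", "NEO20", "TIPI", "BFFM", "BFFM"),
    project = c("Gosling-Potter", "Gosling-Potter", "Rentfrow-Potter",
                "MyPersonality", "CCAP", "SAPA", "SAPA"),
    period_start = c(1999, 2005, 2002, 2008, 2007, 2006, 2010),
    period_end = c(2005, 2009, 2009, 2010, 2008, 2010, 2015),
    stringsAsFactors = FALSE
  )
}
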
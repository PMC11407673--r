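#!/usr/bin/env Rscript
# Stage 3: covariate preparation.
#
# Screens the six site covariates for collinearity with Spearman rank
# correlations (|rho| >= 0.70 flags a pair) and z-transforms them for
# modeling, storing the transform parameters for later spatial projection.

library(camoccu)

cov <- read_covariates("results/data/site_covariates.csv")
cat("stored covariates are",
    if (attr(cov, "standardized")) "already z-scored\n" else "on raw scales\n")

screen <- spearman_screen(cov, threshold = 0.70)
print(screen)
write.csv(round(screen$rho, 3), "results/spearman_rho.csv")

std <- z_transform(cov)
tp <- transform_params(std)
write.csv(data.frame(covariate = names(tp),
                     mean = sapply(tp, `[[`, "mean"),
                     sd = sapply(tp, `[[`, "sd")),
          "results/transform_params.csv", row.names = FALSE)

cat(sprintf("max |rho| = %.3f; %d pair(s) flagged -> %s\n",
            max(abs(screen$rho[upper.tri(screen$rho)])),
            nrow(screen$flagged_pairs),
            if (nrow(screen$flagged_pairs)) "drop one of each pair"
            else "all covariates retained"))
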
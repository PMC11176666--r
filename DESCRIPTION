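Package: stressrank
Title: Social Rank and Chronic-Stress Responses in Primate Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing how dominance rank shapes physiological and
    behavioral responses to chronic stress in small primate colonies.
    Implements David's score dominance ranking from directed agonistic
    interaction matrices with min-max normalization and high-/low-ranking
    classification; split-plot (two-way mixed) repeated-measures ANOVA with
    Mauchly's sphericity test, Greenhouse-Geisser correction and partial
    eta-squared; Holm-adjusted paired post hoc contrasts; a rank-within-group
    pooled ("rank-collapsed") correlation for multi-colony data; first-order
    partial correlation; directed-dyad interaction typing (LL/HL/LH/HH) and
    baseline-appearance stratification; and a synthetic-colony generator that
    plants dominance hierarchies and rank-dependent stress effects so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
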
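Package: troutrisk
Title: Dietary Health Risk Assessment for Heavy Metals in Farmed Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing human health risk from dietary intake of
    heavy metals (As, Cu, Pb, Zn) via fish consumption, built around the
    monitoring design used for rainbow trout farms on the Tishgo River near
    the La Oroya smelter (Peru): bioconcentration (BCF) and biosediment
    accumulation (BSAF) factors, the deterministic exposure chain (estimated
    daily and weekly intake, target hazard quotients, hazard index,
    carcinogenic risk and total cancer risk), Monte Carlo propagation of
    concentration uncertainty with exceedance-probability estimation,
    screening against regulatory maximum limits (FAO/WHO, FSANZ, USEPA,
    CEQG-ISQG), nonparametric group statistics (Kruskal-Wallis, one-sample
    Wilcoxon versus limits, Spearman correlation), and a calibrated
    synthetic-data generator reproducing the three-sector, three-matrix,
    twelve-replicate study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
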
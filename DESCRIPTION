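Package: ddcurve
Title: Delay-Discounting Staircase Tasks, Discounting Curves, and Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adjusting-amount delay-discounting experiments: simulate
    and replay the six-trial titration staircase that yields indifference
    points, fit hyperbolic discounting functions, compute the normalized area
    under the empirical discounting curve (AuC) and the inconsistent-preference
    count, and run the group-level statistics used in lesion studies of
    intertemporal choice (three-way mixed ANOVA with partial eta squared,
    Fisher LSD post hocs, pooled-variance t-tests from summary statistics,
    Pearson chi-square, and default-prior JZS Bayes factors). A synthetic
    cohort generator emulates a patients-versus-controls study design with
    episodic future thinking cueing and two reward magnitudes, so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
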
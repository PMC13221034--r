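Package: cueconflict3d
Title: Shape Versus Texture Bias with Three-Dimensional Shading Cues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring shape versus texture bias in visual
    classifiers and simulated human observers using cue-conflict stimuli
    that either include or exclude three-dimensional shading and attached
    shadows. Provides procedural generators for part-based 3D shape
    families and category-specific textures, a software rasterizer with
    Lambertian shading and shadow-ray attached shadows, texture
    substitution operators that build matched 3D/2D stimulus datasets,
    entry-level softmax aggregation and bias statistics for arbitrary
    classifiers, trial-schedule builders and observer simulation with 2x2
    repeated-measures ANOVA, and a four-curriculum finetuning protocol
    (image filter by freeze policy) with early stopping, exercised on a
    small trainable reference classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
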
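Package: oomil
Title: Ordinal Multi-Instance Learning with Key-Instance Selection for
    Mammogram-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised three-class (normal < benign < cancer)
    classification of grayscale images carrying only a bag-level ordinal
    label. Each image is tiled into a bag of patches; a small convolutional
    network scores every patch; the k minimum-loss "key instances" per bag
    are assigned the bag label and trained with an all-threshold ordinal
    uncertainty loss with learnable cutpoints. Includes a synthetic
    mammogram-like image generator with instance-level ground truth, the
    full bag-construction pipeline (grid patching, foreground threshold
    filtering, flip/rotate balancing, bilinear resize), an ordered
    binary-decomposition baseline trainer, instance-level evaluation
    metrics, and key-instance selection diagnostics and visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
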
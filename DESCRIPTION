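Package: patchentropy
Title: Patch-Entropy Structural Descriptors for Multimodal Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural descriptor images for multimodal medical image
    similarity and registration. Each pixel of a grayscale image is replaced
    by the uncertainty of its local patch intensity distribution, measured by
    one of four strictly concave core functions: Shannon entropy, logarithmic
    fuzzy entropy, exponential fuzzy entropy, or a rational concave function.
    The resulting descriptor images form a common "third modality" in which
    images of different contrast mechanisms can be compared by mean absolute
    difference. Includes spatially weighted and Parzen-window patch histogram
    estimation, rigid similarity-curve search, slice matching with deflection
    statistics, discrete deformation selection, and generators for synthetic
    multimodal phantoms used to exercise the method end to end.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
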
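Package: waveseg
Title: Multi-Encoder 3D MRI Segmentation with Wavelet Fusion and Global
    Context Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for multimodal 3D brain-tumor segmentation in the BraTS
    convention (T1, T1ce, T2, FLAIR volumes with nested whole-tumor,
    tumor-core and enhancing-tumor regions). Implements a five-level
    multi-encoder/single-decoder convolutional network in which per-modality
    encoder features are fused in the wavelet domain (single-level separable
    3D discrete wavelet transform; low-frequency subbands averaged,
    high-frequency subbands summed) and global context is injected at deep
    levels through a softmax attention-pooling block with a bottleneck
    transform. Includes a synthetic multimodal phantom generator with nested
    ellipsoidal tumor sub-regions, NIfTI input/output, z-score normalisation,
    random crop and mirror-flip/intensity-shift augmentation, combined binary
    cross-entropy and soft-Dice training with Adam and polynomial
    learning-rate decay, Dice and 95th-percentile Hausdorff evaluation, and
    the small-enhancing-tumor relabelling post-processing protocol. Training
    and inference run on the CPU via a compact reverse-mode automatic
    differentiation tape with compiled convolution, resampling and distance
    transform kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
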
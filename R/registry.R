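#' Radiomic feature registry
#'
#' The catalogue of the 42 texture features computed by the package:
#' 8 gray-level co-occurrence (GLCM), 13 gray-level run-length (GLRLM),
#' 3 intensity-statistics (IS), 5 neighborhood gray-tone difference
#' (NGTDM) and 13 gray-level size-zone (GLSZM) features, each with its
#' IBSI reference code (where one exists) and the volume-normalization
#' type applied to it (`"none"`, `"1"` = divide by volume, `"2"` =
#' multiply by volume, `"3"`/`"4"` = probability-renormalized busyness /
#' coarseness). Exactly seven features are volume-normalized.
#'
#' @return tibble with columns `feature` (unique id, family-prefixed),
#'   `family`, `name`, `ibsi_code` and `vn_type`.
#' @examples
#' dplyr::count(feature_registry(), family)
#' @export
feature_registry <- function() {
  reg <- tibble::tribble(
    ~family, ~name, ~ibsi_code, ~vn_type,
    "GLCM",  "Contrast",      "ACUI", "none",
    "GLCM",  "Correlation",   "NI2N", "none",
    "GLCM",  "Dissimilarity", "8S9J", "none",
    "GLCM",  "Energy",        "8ZQL", "none",
    "GLCM",  "Entropy",       "TU9B", "none",
    "GLCM",  "Homogeneity",   "IB1Z", "none",
    "GLCM",  "SumAverage",    "ZGXS", "none",
    "GLCM",  "Variance",      "UR99", "none",
    "GLRLM", "GLN",           "R5YN", "1",
    "GLRLM", "GLV",           "8CE5", "none",
    "GLRLM", "HGRE",          "G3QZ", "none",
    "GLRLM", "LRE",           "W4KF", "none",
    "GLRLM", "LRHGE",         "3KUM", "none",
    "GLRLM", "LRLGE",         "IVPO", "none",
    "GLRLM", "LGRE",          "V3SW", "none",
    "GLRLM", "RLV",           "SXLW", "none",
    "GLRLM", "RP",            "9ZK5", "none",
    "GLRLM", "RLN",           "W92Y", "1",
    "GLRLM", "SRE",           "220V", "none",
    "GLRLM", "SRHGE",         "GD3A", "none",
    "GLRLM", "SRLGE",         "HTZT", "none",
    "IS",    "Kurtosis",      "IPH6", "none",
    "IS",    "Skewness",      "KE2A", "none",
    "IS",    "Variance",      "ECT3", "none",
    "NGTDM", "Busyness",      "NQ30", "3",
    "NGTDM", "Coarseness",    NA,     "4",
    "NGTDM", "Complexity",    "HDEZ", "none",
    "NGTDM", "Contrast",      "65HE", "none",
    "NGTDM", "Strength",      NA,     "2",
    "GLSZM", "GLN",           "JNSA", "1",
    "GLSZM", "GLV",           "BYLV", "none",
    "GLSZM", "HGZE",          "5GN9", "none",
    "GLSZM", "LZE",           "48P8", "none",
    "GLSZM", "LZHGE",         "J17V", "none",
    "GLSZM", "LZLGE",         "YH51", "none",
    "GLSZM", "LGZE",          "XMSY", "none",
    "GLSZM", "SZE",           "5QRC", "none",
    "GLSZM", "SZHGE",         "HW1V", "none",
    "GLSZM", "SZLGE",         "5RAI", "none",
    "GLSZM", "ZP",            "P30P", "none",
    "GLSZM", "ZSN",           "4JP3", "1",
    "GLSZM", "ZSV",           "3NSA", "none"
  )
  dplyr::mutate(reg, feature = paste(.data$family, .data$name, sep = "_"),
                .before = 1)
}
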
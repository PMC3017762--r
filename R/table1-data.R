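# The published Ka/Ks and divergence table for the rice PTR family's
# duplicated paralog pairs, transcribed as a reference dataset. Ka and Ks are
# the published (codeml-derived) values; `ratio` is the published Ka/Ks as
# printed; `interval_genes` is NA for segmental pairs.

#' Published paralog Ka/Ks reference table
#'
#' The 19 duplicated paralog pairs of the rice PTR (peptide transporter)
#' family with their published Ka, Ks, Ka/Ks, purifying-selection flag,
#' divergence fate (D/NOF/SF/NF; `unclassified` where the survey had no
#' probe data), duplication type, subfamily, protein identity, and number of
#' intervening genes. Used as the printed-input reference for ratio
#' recomputation and composition checks.
#'
#' @return A 19-row tibble.
#' @export
ptr_paralog_table <- function() {
  tribble_df <- tibble::tribble(
    ~gene_a, ~gene_b, ~ka, ~ks, ~ratio, ~purifying, ~fate, ~duplicate_type, ~subfamily, ~identity, ~interval_genes,
    "Os02g37040", "Os04g39030", 0.119, 1.333, 0.0892, TRUE, "NF", "segmental", "V", 76.1, NA_integer_,
    "Os02g48570", "Os06g21900", 0.247, 10.084, 0.0245, TRUE, "NF", "segmental", "I", 55.0, NA_integer_,
    "Os03g04570", "Os10g33170", 0.137, 2.312, 0.0593, TRUE, "SF", "segmental", "II", 70.6, NA_integer_,
    "Os01g55600", "Os01g55610", 0.412, 57.191, 0.0072, TRUE, "D", "tandem", "IV", 44.0, 0L,
    "Os01g65100", "Os01g65110", 0.178, 1.721, 0.1035, TRUE, "NF", "tandem", "II", 64.3, 0L,
    "Os01g65150", "Os01g65169", 0.090, 0.370, 0.2429, TRUE, "D", "tandem", "II", 82.5, 0L,
    "Os01g65200", "Os01g65210", 0.304, 1.141, 0.2662, TRUE, "NOF", "tandem", "II", 30.1, 0L,
    "Os01g67630", "Os01g67640", 0.087, 0.525, 0.1653, TRUE, "NF", "tandem", "I", 61.6, 0L,
    "Os03g13240", "Os03g13250", 0.233, 1.981, 0.1175, TRUE, "SF", "tandem", "I", 62.6, 0L,
    "Os04g41400", "Os04g41450", 0.153, 0.975, 0.1565, TRUE, "SF", "tandem", "III", 75.2, 3L,
    "Os04g50940", "Os04g50950", 0.085, 0.611, 0.1397, TRUE, "SF", "tandem", "I", 82.1, 0L,
    "Os05g33960", "Os05g34000", 0.183, 1.262, 0.1447, TRUE, "NOF", "tandem", "IV", 62.6, 3L,
    "Os05g34010", "Os05g34030", 0.183, 3.869, 0.0473, TRUE, "NOF", "tandem", "IV", 65.4, 1L,
    "Os05g35594", "Os05g35650", 0.247, 1.884, 0.1313, TRUE, "unclassified", "tandem", "II", 55.4, 3L,
    "Os06g13200", "Os06g13210", 0.038, 0.274, 0.1371, TRUE, "unclassified", "tandem", "II", 89.5, 0L,
    "Os06g49220", "Os06g49250", 0.082, 0.387, 0.2124, TRUE, "NOF", "tandem", "I", 79.9, 2L,
    "Os10g02240", "Os10g02260", 0.290, 1.856, 0.1565, TRUE, "NF", "tandem", "I", 56.5, 1L,
    "Os11g18044", "Os11g18110", 0.149, 0.675, 0.2201, TRUE, "SF", "tandem", "III", 65.4, 3L,
    "Os12g44100", "Os12g44110", 0.177, 0.592, 0.2988, TRUE, "NF", "tandem", "IV", 70.9, 0L
  )
  tribble_df
}
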
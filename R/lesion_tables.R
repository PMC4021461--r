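#' Published differential-expression tables of the striatal lesion study
#'
#' The per-timepoint tables of differentially expressed striatal proteins
#' after 6-OHDA lesioning, as printed (protein name, accession, mean iTRAQ
#' ratio +/- SD, peptide count, p-value), packaged for regression tests of
#' table formatting, sorting and filter behavior. Rows appear in printed
#' order: the down-regulated block first, then the up-regulated block, each
#' ascending by mean ratio. Every row respects the fold-change band
#' (mean >= 1.25 or <= 0.75 at the printed precision) and the >= 3 peptide
#' rule; a handful of printed p-values sit slightly above 0.05, so the
#' printed tables are not a strict output of the stated p < 0.05 rule — the
#' pipeline follows the stated rule and these rows document the discrepancy.
#'
#' Note the same accession can recur across timepoints (GFAP and guanine
#' deaminase appear at all three), and distinct accessions with the same
#' protein name are distinct entries (two Rab-3C accessions at 3 days).
#'
#' @param contrast optional contrast label (`"115/114"`, `"116/114"`,
#'   `"117/114"`) to return a single timepoint's table.
#' @return A tibble with columns `protein_name`, `accession`, `contrast`,
#'   `timepoint`, `direction`, `mean_ratio`, `sd`, `n_peptides`, `p_value`.
#' @examples
#' dplyr::filter(lesion_tables("115/114"), accession == "158186732")
#' @export
lesion_tables <- function(contrast = NULL) {
  out <- lesion_table_rows()
  out$timepoint <- contrast_timepoint(out$contrast)
  out <- out[, c(
    "protein_name", "accession", "contrast", "timepoint", "direction",
    "mean_ratio", "sd", "n_peptides", "p_value"
  )]
  if (!is.null(contrast)) {
    stopifnot(contrast %in% contrast_labels())
    out <- out[out$contrast == contrast, ]
  }
  out
}

# printed rows, embedded verbatim (ratios are lesioned/control)
lesion_table_rows <- function() {
  tibble::tribble(
  ~protein_name, ~accession, ~contrast, ~direction, ~mean_ratio, ~sd, ~n_peptides, ~p_value,
  "Diacylglycerol kinase beta", "9506535", "115/114", "down", 0.57, 0.2, 4L, 0.0192,
  "Synaptophysin", "6981622", "115/114", "down", 0.59, 0.18, 5L, 0.0035,
  "Synaptic ras GTPase-activating protein p135 SynGAP", "2935448", "115/114", "down", 0.62, 0.1, 7L, 2.92E-05,
  "Ras-related protein Rab-3C", "19424194", "115/114", "down", 0.67, 0.13, 5L, 0.0029,
  "Protein NipSnap homolog 2", "62945328", "115/114", "down", 0.67, 0.06, 3L, 0.0066,
  "Prohibitin", "6679299", "115/114", "down", 0.67, 0.26, 6L, 0.0069,
  "Succinyl-CoA synthetase alpha subunit", "204356", "115/114", "down", 0.69, 0.26, 5L, 0.0486,
  "RII-B-binding protein", "557585", "115/114", "down", 0.69, 0.12, 4L, 0.0074,
  "Type II cAMP-dependent protein kinase regulatory subunit", "206671", "115/114", "down", 0.70, 0.14, 16L, 3.45E-08,
  "A-kinase anchor protein 5", "19424156", "115/114", "down", 0.71, 0.22, 5L, 0.0276,
  "RNA binding protein p37 AUF1", "9588102", "115/114", "down", 0.71, 0.3, 6L, 0.0325,
  "Erythrocyte adducin subunit beta", "10720378", "115/114", "down", 0.72, 0.12, 6L, 0.0010,
  "Septin-5", "90577179", "115/114", "down", 0.72, 0.09, 7L, 0.0001,
  "Reticulon-3 isoform A", "57977297", "115/114", "down", 0.72, 0.18, 5L, 0.0151,
  "Homer protein homolog 1", "13928988", "115/114", "down", 0.73, 0.26, 6L, 0.0484,
  "Ras-related protein Rab-3C", "13470090", "115/114", "down", 0.74, 0.15, 5L, 0.0093,
  "V-type proton ATPase 116 kDa subunit a isoform 1", "139352", "115/114", "down", 0.75, 0.22, 8L, 0.0107,
  "Tenascin-R precursor", "6981668", "115/114", "up", 1.25, 0.64, 8L, 0.0545,
  "Cytoplasmic dynein 1 light intermediate chain 1", "21955134", "115/114", "up", 1.25, 0.12, 3L, 0.0409,
  "Rap1b", "595280", "115/114", "up", 1.25, 0.08, 4L, 0.0048,
  "G protein beta 1 subunit", "984553", "115/114", "up", 1.27, 0.36, 7L, 0.0373,
  "6-phosphofructokinase, muscle type", "13929002", "115/114", "up", 1.27, 0.47, 8L, 0.0482,
  "Transketolase", "12018252", "115/114", "up", 1.27, 0.32, 6L, 0.0429,
  "Guanine deaminase", "148747414", "115/114", "up", 1.30, 0.8, 14L, 0.0453,
  "Band 4.1-like protein 3", "16758808", "115/114", "up", 1.31, 0.51, 10L, 0.0145,
  "Similar to 14-3-3 protein sigma", "51260816", "115/114", "up", 1.34, 0.3, 5L, 0.0378,
  "Eukaryotic initiation factor 4A-I isoform 1", "4503529", "115/114", "up", 1.34, 0.25, 4L, 0.0425,
  "Reticulon-4", "13929188", "115/114", "up", 1.36, 0.26, 6L, 0.0080,
  "Dihydropyrimidinase-related protein 4", "3122037", "115/114", "up", 1.38, 0.35, 7L, 0.0117,
  "cGMP-dependent 3',5'-cyclic phosphodiesterase isoform 2", "13592021", "115/114", "up", 1.45, 0.64, 6L, 0.0544,
  "Glutathione S-transferase P", "25453420", "115/114", "up", 1.48, 0.18, 4L, 0.0067,
  "Cytosol aminopeptidase", "58865398", "115/114", "up", 1.53, 0.4, 5L, 0.0166,
  "Glycyl-tRNA synthetase;", "81889021", "115/114", "up", 1.54, 0.24, 3L, 0.0353,
  "Chondroitin sulfate proteoglycan core protein 2", "21431624", "115/114", "up", 1.61, 0.66, 4L, 0.0585,
  "Platelet-activating factor acetylhydrolase IB subunit alpha", "7305363", "115/114", "up", 1.77, 0.4, 3L, 0.0409,
  "NAD-dependent deacetylase sirtuin-2", "56605812", "115/114", "up", 1.78, 0.51, 9L, 0.0005,
  "Carbonic anhydrase 2", "9506445", "115/114", "up", 1.79, 0.54, 6L, 0.0049,
  "Myelin-oligodendrocyte glycoprotein precursor", "158262022", "115/114", "up", 1.85, 0.2, 5L, 0.0005,
  "Myelin proteolipid protein", "13591880", "115/114", "up", 1.85, 0.62, 17L, 5.15E-06,
  "Myelin basic protein", "4454317", "115/114", "up", 1.86, 0.59, 14L, 1.84E-05,
  "PMES-2C", "55700833", "115/114", "up", 1.87, 0.62, 4L, 0.0307,
  "Alpha-internexin", "9506811", "115/114", "up", 1.87, 0.54, 18L, 1.5E-07,
  "NF-M protein", "205688", "115/114", "up", 1.90, 0.53, 19L, 8.36E-09,
  "Myelin basic protein isoform 4", "70166270", "115/114", "up", 1.92, 0.61, 15L, 4.4E-06,
  "Neurofilament light polypeptide", "13929098", "115/114", "up", 1.92, 0.64, 11L, 4.56E-05,
  "2',3'-cyclic-nucleotide 3'-phosphodiesterase", "57977323", "115/114", "up", 1.92, 0.59, 29L, 5.17E-11,
  "High molecular-weight neurofilament", "2642598", "115/114", "up", 1.98, 0.75, 8L, 0.0006,
  "Glycerol-3-phosphate dehydrogenase [NAD+], cytoplasmic", "57527919", "115/114", "up", 1.99, 0.32, 3L, 0.0216,
  "Glial fibrillary acidic protein", "158186732", "115/114", "up", 3.44, 2.58, 8L, 0.0118,
  "Protein phosphatase 1 regulatory subunit 1B (DARPP32)", "61889054", "116/114", "down", 0.60, 0.37, 6L, 0.0321,
  "Complexin-2", "5729783", "116/114", "down", 0.62, 0.13, 4L, 0.0057,
  "Adh5 protein", "54035294", "116/114", "down", 0.64, 0.14, 3L, 0.0335,
  "cAMP and cAMP-inhibited cGMP 3',5'-cyclic phosphodiesterase 10A", "13489075", "116/114", "down", 0.71, 0.30, 9L, 0.0018,
  "NADH dehydrogenase [ubiquinone] iron-sulfur protein 4", "68341995", "116/114", "down", 0.73, 0.14, 3L, 0.0507,
  "Microsomal Cytochrome B5", "6980893", "116/114", "down", 0.74, 0.06, 3L, 0.0115,
  "Neuron-specific calcium-binding protein hippocalcin", "6754240", "116/114", "down", 0.74, 0.18, 8L, 0.0042,
  "Macrophage migration inhibitory factor", "694108", "116/114", "up", 1.25, 0.14, 3L, 0.0537,
  "Guanine nucleotide-binding protein G(z) subunit alpha", "6980966", "116/114", "up", 1.27, 0.10, 3L, 0.0304,
  "Clathrin-associated protein 17", "1809320", "116/114", "up", 1.30, 0.14, 3L, 0.0399,
  "ApoE", "202959", "116/114", "up", 1.32, 0.20, 4L, 0.0278,
  "Brain acid soluble protein 1", "11560135", "116/114", "up", 1.33, 0.71, 10L, 0.0292,
  "Gamma-enolase", "26023949", "116/114", "up", 1.33, 0.75, 16L, 0.0165,
  "Astrocytic phosphoprotein PEA-15", "4505705", "116/114", "up", 1.34, 0.28, 4L, 0.0481,
  "Microtubule-associated protein RP/EB family member 3", "39930509", "116/114", "up", 1.39, 0.65, 6L, 0.0479,
  "Platelet-activating factor acetylhydrolase IB subunit alpha", "7305363", "116/114", "up", 1.39, 0.09, 3L, 0.0130,
  "Beta-enolase", "126723393", "116/114", "up", 1.40, 0.96, 10L, 0.0400,
  "Synaptic vesicle glycoprotein 2B", "17105360", "116/114", "up", 1.44, 0.26, 6L, 0.0042,
  "Thiomorpholine-carboxylate dehydrogenase", "16758840", "116/114", "up", 1.46, 0.33, 4L, 0.0312,
  "Protein IMPACT", "58866042", "116/114", "up", 1.49, 0.12, 3L, 0.0126,
  "Sorting and assembly machinery component 50 homolog", "51948454", "116/114", "up", 1.59, 0.21, 3L, 0.0233,
  "Guanine deaminase", "148747414", "116/114", "up", 1.59, 1.04, 14L, 0.0097,
  "LanC-like protein 2", "62079109", "116/114", "up", 1.73, 0.30, 4L, 0.0094,
  "Glial fibrillary acidic protein", "158186732", "116/114", "up", 1.94, 0.87, 8L, 0.0047,
  "Importin subunit beta-1", "8393610", "117/114", "down", 0.59, 0.37, 5L, 0.0407,
  "Complexin-2", "5729783", "117/114", "down", 0.59, 0.16, 4L, 0.0068,
  "Annexin A6", "130502086", "117/114", "down", 0.61, 0.37, 7L, 0.0263,
  "Myelin basic protein isoform 4", "70166270", "117/114", "down", 0.67, 0.21, 15L, 3.27E-06,
  "Protein phosphatase 1 regulatory subunit 1B (DARPP32)", "61889054", "117/114", "down", 0.67, 0.15, 6L, 0.0019,
  "Myelin basic protein", "4454317", "117/114", "down", 0.68, 0.24, 14L, 2.76E-05,
  "Plasma membrane calcium-transporting ATPase 3", "158138481", "117/114", "down", 0.69, 0.14, 6L, 0.0018,
  "Cystatin C", "227013", "117/114", "down", 0.71, 0.14, 3L, 0.0522,
  "High molecular-weight neurofilament", "2642598", "117/114", "down", 0.73, 0.27, 8L, 0.0074,
  "Myelin-oligodendrocyte glycoprotein precursor", "158262022", "117/114", "down", 0.73, 0.08, 5L, 0.0011,
  "Myelin proteolipid protein", "13591880", "117/114", "down", 0.74, 0.24, 17L, 0.0001,
  "cAMP and cAMP-inhibited cGMP 3',5'-cyclic phosphodiesterase 10A", "13489075", "117/114", "down", 0.74, 0.24, 9L, 0.0039,
  "3',5'-cyclic nucleotide phosphodiesterase 1B", "12083681", "117/114", "down", 0.75, 0.26, 9L, 0.0091,
  "Mu Class Glutathione S-Transferase", "442967", "117/114", "up", 1.25, 0.22, 9L, 0.0050,
  "Chain A, Tetra-(5-Fluorotryptophanyl)-Glutathione Transferase", "4388948", "117/114", "up", 1.25, 0.22, 9L, 0.0051,
  "Chain A, Tetradeca-(3-Fluorotyrosyl)- Glutathione S-Transferase", "5107744", "117/114", "up", 1.26, 0.25, 7L, 0.0182,
  "NADH dehydrogenase (ubiquinone) 1 alpha subcomplex 10-like", "32996721", "117/114", "up", 1.27, 0.16, 4L, 0.0244,
  "V-type proton ATPase subunit B, brain isoform", "17105370", "117/114", "up", 1.27, 0.39, 9L, 0.0250,
  "Voltage dependent anion channel", "4105605", "117/114", "up", 1.27, 0.42, 10L, 0.0248,
  "Hyaluronan and proteoglycan link protein 1", "1346731", "117/114", "up", 1.27, 0.32, 6L, 0.0402,
  "RNA binding protein p37 AUF1", "9588102", "117/114", "up", 1.29, 0.48, 6L, 0.0565,
  "Clathryn light chain (LCA2)", "203276", "117/114", "up", 1.29, 0.20, 4L, 0.0336,
  "Synapsin-1 isoform b", "160707907", "117/114", "up", 1.29, 0.43, 18L, 0.0020,
  "Neural cell adhesion molecule long domain form", "281037", "117/114", "up", 1.31, 0.48, 6L, 0.0516,
  "Glutathione S-transferase Yb-3", "13592152", "117/114", "up", 1.31, 0.28, 7L, 0.0116,
  "Synapsin-2 isoform 1", "77404242", "117/114", "up", 1.33, 0.30, 12L, 0.0007,
  "ADP-ribosylation factor 5", "4502209", "117/114", "up", 1.36, 0.16, 3L, 0.0359,
  "Guanine deaminase", "148747414", "117/114", "up", 1.40, 0.83, 14L, 0.0126,
  "Glial fibrillary acidic protein", "158186732", "117/114", "up", 1.53, 1.00, 8L, 0.0321,
  "Thiomorpholine-carboxylate dehydrogenase", "16758840", "117/114", "up", 1.53, 0.49, 4L, 0.0592,
  "LanC-like protein 2", "62079109", "117/114", "up", 1.54, 0.43, 4L, 0.0406,
  "Synaptic vesicle glycoprotein 2B", "17105360", "117/114", "up", 1.56, 0.44, 6L, 0.0088,
  "Sorting and assembly machinery component 50 homolog", "51948454", "117/114", "up", 1.94, 0.58, 3L, 0.0524
)
}
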
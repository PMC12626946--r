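#' Worked micro example dataset
#'
#' A fixed two-complex, four-chain synthetic dataset embedded literally in
#' the package, used by I/O, padding, loss and metric examples and unit
#' tests where exact values matter. All chains are within the 110-130
#' residue variable-domain window; the dataset holds 490 residues of which
#' 51 are binding, a binding fraction of 51/490 = 0.10408163.
#'
#' @return A `labeled_dataset` of 2 complexes (4 chains).
#' @export
#' @examples
#' dataset_summary(generate_worked_micro_example())
generate_worked_micro_example <- function() {
  rec <- list(
    list("SYN0001", "H",
         "NWYIVRGSEMGCEGMITQEDPKIWGKCNILQISVFGDKSISVVIGLPHGYESTMPNVATANMSCKTIKKYQMYWYDVPVMCYCVIFTSKRMYHQIYSAPELHNPHWELTGNQMKIAMLV",
         "00000000000000000000000110000000000000000000000011000000000000000000000001100000000000000001111110000000000000000000000"),
    list("SYN0001", "L",
         "IPVSGIRYMKKHPEIDQNQFPDWMRTAWPMGLHSGCQHDVLVNRFEQIYTSQCYDDDCEIRVNSYYGTDQTFGQQLYLLADKRADFHMLYRAKWVLSHLWAKHYNYEFEVSRKCYHAASYCKLT",
         "0000000000000000000000000000000000000000000000000000000000000011111000000000000000000001111000000000001111000000000000000000"),
    list("SYN0002", "H",
         "LECAVPYPPLQPEMMNWPHYMREKLYALTWCRDQEINIFHGRSWSKHKVQWKYHCYDEGETLESNRNQDLPAHIAGSFVGYTEMLCMVFKVTMTMTKVIEDRYYWPGASACHDFAVAWQGECNN",
         "0000000000000000000000001100000000000000000000000000000011100000000000000001100000000000000000000001111110000000000000000000"),
    list("SYN0002", "L",
         "PQMYCEGYFYMTQQARKPQAALGPAIIGSNVITKYWACDPCKRDLNTMEECMWDYSEGVWYWNDDVMGPRDKKQPPVPYGNRIVMGEHWCDDIHVMTEDYWDWCRFPCGYSSEYIHGLTEHVQ",
         "011110000000000000000000011111000000000000000000000011110000000000000000000000000000000000000000000000000000000000000000000")
  )
  chains <- lapply(rec, function(r) labeled_chain(r[[1]], r[[2]], r[[3]], r[[4]]))
  labeled_dataset(
    list(antibody_complex(chains[[1]], chains[[2]]),
         antibody_complex(chains[[3]], chains[[4]])),
    provenance = "worked micro example (fixed literal synthetic data)"
  )
}
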
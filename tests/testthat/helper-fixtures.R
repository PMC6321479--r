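# shared fixtures built in code

construct_fasta <- function() {
  system.file("extdata", "c_lrta_construct.fasta", package = "idpbiophys")
}

construct_seq <- function() read_fasta(construct_fasta())

# monomer mass of the construct, kDa
MONOMER_KDA <- 12.44989

# exact two-anchor SEC calibration from the reference elution pairs
anchor_calibration <- function() {
  sec_anchor_calibration(c(11.98, 13.88), c(100, 31.6))
}
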
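# small deterministic fixtures shared across test files

toy_genotypes <- function() {
  # 2 populations x 2 individuals, 2 loci, hand-checkable
  genotype_table(data.frame(
    sample_id = paste0("i", 1:4),
    species = "sp1",
    population = rep(c("p1", "p2"), each = 2),
    L1.1 = c(1, 1, 2, 2), L1.2 = c(1, 2, 2, 2),
    L2.1 = c(1, 1, 1, 2), L2.2 = c(1, 1, 2, 2),
    check.names = FALSE))
}

# balanced 4-tip tree: ((t1:1,t2:1):1,(t3:1,t4:1):1);
balanced4 <- function() {
  ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
}

star_tree <- function(n, depth = 1) {
  ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":", depth,
                                           collapse = ","), ");"))
}

flat_spectra <- function(value = 0.5, n = 2, wl = seq(400, 2500, by = 3)) {
  spectra_set(matrix(value, n, length(wl)), wl)
}
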
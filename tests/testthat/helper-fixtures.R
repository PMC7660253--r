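# Fixtures built in code: tiny hand-checkable objects shared across tests.

# 4-strain toy panel, baseline diploid: S1 gains A, S2 loses C, S3 gains A,
# S4 euploid. Hand enumeration over aneuploid strains {S1,S2,S3}:
# f(A) = 2/1, f(B) = 0/3, f(C) = 1/2.
toy_copy_matrix <- function() {
  copy_number_matrix(matrix(
    c(3L, 2L, 2L,
      2L, 2L, 1L,
      3L, 2L, 2L,
      2L, 2L, 2L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("S", 1:4), c("A", "B", "C"))),
    baseline_ploidy = 2L)
}

# Two chromosomes, four genes: three on chrA, one on chrB.
toy_map <- function() {
  genome_map(
    data.frame(chrom = c("chrA", "chrB"), length = c(100000L, 50000L)),
    data.frame(gene = c("a1", "a2", "a3", "b1"),
               chrom = c("chrA", "chrA", "chrA", "chrB"),
               start = c(100L, 2000L, 5000L, 300L),
               end = c(900L, 2900L, 5900L, 1200L),
               strand = c("+", "-", "+", "-")))
}

# Three chromosomes X, Y, Z with hand-summable genetic interactions
# (scores exactly representable in binary so the X/Z tie from Y is exact):
# S(X,Y) = 0.5 - 0.25 = 0.25, S(X,Z) = -0.75, S(Y,Z) = 0.25.
hand_epistasis_fixture <- function() {
  map <- genome_map(
    data.frame(chrom = c("X", "Y", "Z"), length = rep(50000L, 3)),
    data.frame(gene = c("x1", "x2", "y1", "y2", "z1"),
               chrom = c("X", "X", "Y", "Y", "Z"),
               start = c(10L, 200L, 10L, 200L, 10L),
               end = c(100L, 300L, 100L, 300L, 100L),
               strand = "+"))
  gi <- interaction_table(data.frame(
    gene_a = c("x1", "x2", "x1", "y2"),
    gene_b = c("y1", "y1", "z1", "z1"),
    score = c(0.5, -0.25, -0.75, 0.25)), kind = "genetic")
  list(map = map, gi = gi)
}

# Independent brute-force oracle for the least-epistasis arrow rule:
# for each row, scan all |S| values and keep the lexicographically smallest
# target among the minima.
oracle_least_epistasis <- function(S) {
  chroms <- rownames(S)
  edges <- NULL
  for (i in chroms) {
    best <- NULL
    best_abs <- Inf
    for (j in sort(chroms)) {
      if (i == j || is.na(S[i, j])) next
      if (abs(S[i, j]) < best_abs) {
        best <- j
        best_abs <- abs(S[i, j])
      }
    }
    if (!is.null(best)) {
      edges <- rbind(edges, data.frame(source = i, target = best))
    }
  }
  edges
}
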
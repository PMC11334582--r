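# small fixtures built in code

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 12L,
                3L, 7L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("smpA", "smpB"), c("t1", "t2", "t3")))
  m
}

toy_taxonomy <- function() {
  data.frame(
    taxon_id = c("t1", "t2", "t3"),
    domain = "Bacteria", phylum = "p1",
    class = c("c1", "c1", "c2"),
    order = c("o1", "o1", "o2"),
    family = c("f1", "f1", "f2"),
    genus = c("g1", "g2", "g3"),
    stringsAsFactors = FALSE
  )
}

toy_count_table <- function() count_table(toy_counts(), toy_taxonomy())

write_toy_count_tsv <- function(m = toy_counts(), path = tempfile(fileext = ".tsv")) {
  df <- data.frame(taxon_id = colnames(m), t(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_toy_taxonomy_tsv <- function(tax = toy_taxonomy(),
                                   path = tempfile(fileext = ".tsv")) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# two groups of two with tight within-pair and distant between-pair samples
toy_permanova_dist <- function() {
  m <- matrix(10, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 0
  m
}

# independent sums-of-squares oracle used to enumerate permutation nulls
oracle_pseudo_f <- function(d, groups) {
  d2 <- d^2
  n <- nrow(d)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    ss_w <- ss_w + sum(d2[ix, ix, drop = FALSE]) / (2 * length(ix))
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

quiet_rarefied <- function(...) suppressWarnings(rarefied_metric(...))
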
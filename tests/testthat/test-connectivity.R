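test_that("rank profiles sort descending with lexical tie-breaks", {
  expect_equal(rank_profile(c(A = 2, B = 1))$ranks, c(A = 1L, B = 2L))
  expect_equal(rank_profile(c(C = 1, A = 1, B = 1))$ranks,
               c(C = 3L, A = 1L, B = 2L))
  # 5-gene toy with one tie, ranked by hand: D(5) > B(3) = E(3) > A(2) > C(0)
  r <- rank_profile(c(A = 2, B = 3, C = 0, D = 5, E = 3))
  expect_equal(r$ranks, c(A = 4L, B = 2L, C = 5L, D = 1L, E = 3L))
  expect_error(rank_profile(c(A = 1, A = 2)), "unique")
  expect_error(rank_profile(c(A = NaN, B = 1)), "finite")
})

test_that("profile averaging is the unweighted per-gene mean", {
  one <- list(compound_id = "c1", values = list(c(g1 = 1, g2 = 2)))
  expect_equal(average_compound_profiles(one)$c1, c(g1 = 1, g2 = 2))
  cancel <- list(compound_id = c("c1", "c1"),
                 values = list(c(g1 = 1, g2 = -2), c(g1 = -1, g2 = 2)))
  expect_equal(average_compound_profiles(cancel)$c1, c(g1 = 0, g2 = 0))
  three <- list(compound_id = c("c1", "c1", "c1"),
                values = list(c(g1 = 1, g2 = 4), c(g1 = 2, g2 = 5),
                              c(g1 = 6, g2 = 0)))
  expect_equal(average_compound_profiles(three)$c1, c(g1 = 3, g2 = 3))
  expect_error(average_compound_profiles(list(compound_id = c("a", "b"),
    values = list(c(g1 = 1), c(g2 = 1)))), "universe")
})

test_that("enrichment score matches the hand-computed cases", {
  prof <- rank_profile(setNames(10:1, paste0("g", 1:10)))  # g1 rank 1 ... g10 rank 10
  top2 <- enrichment_score(prof, c("g1", "g2"))            # ranks (1,2)
  expect_equal(top2$a, 0.8)
  expect_equal(top2$b, 0.1)
  expect_equal(top2$es, 0.8)
  bot2 <- enrichment_score(prof, c("g9", "g10"))           # ranks (9,10)
  expect_equal(bot2$b, 0.9)
  expect_equal(bot2$es, -0.9)
  expect_error(enrichment_score(prof, character(0)), "empty")
  expect_error(enrichment_score(prof, c("g1", "nope")), "nope")
})

test_that("enrichment score equals the CDF-sweep oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    t <- sample(1:min(10, n), 1)
    genes <- paste0("g", 1:n)
    prof <- rank_profile(setNames(sample(n), genes))
    set <- sample(genes, t)
    got <- enrichment_score(prof, set)
    ref <- es_oracle(unname(prof$ranks[set]), n)
    expect_equal(got$a, ref$a, tolerance = 1e-12)
    expect_equal(got$b, ref$b, tolerance = 1e-12)
    expect_equal(got$es, ref$es, tolerance = 1e-12)
  }
})

test_that("enrichment score is invariant to gene relabeling and stable on the full universe", {
  set.seed(5)
  genes <- paste0("g", 1:30)
  vals <- setNames(rnorm(30), genes)
  prof <- rank_profile(vals)
  set <- sample(genes, 6)
  es1 <- enrichment_score(prof, set)$es
  relab <- setNames(rev(paste0("X", 1:30)), genes)   # bijective relabeling
  prof2 <- rank_profile(setNames(unname(vals), unname(relab[genes])))
  es2 <- enrichment_score(prof2, unname(relab[set]))$es
  expect_equal(es1, es2)
  full1 <- enrichment_score(prof, genes)
  full2 <- enrichment_score(rank_profile(vals), genes)
  expect_identical(full1, full2)
})

test_that("connectivity score follows the sign rule and antisymmetry", {
  expect_equal(connectivity_score(0.8, 0.8), 0)
  expect_equal(connectivity_score(0.8, -0.6), 0.7)
  expect_equal(connectivity_score(-0.5, 0.3), -0.4)
  set.seed(7)
  for (i in 1:50) {
    u <- runif(1, -1, 1); d <- runif(1, -1, 1)
    expect_equal(connectivity_score(d, u), -connectivity_score(u, d))
  }
})

test_that("database querying finds planted reversers and is batch-consistent", {
  query <- gene_set_pair(paste0("UP", 1:10), paste0("DN", 1:10))
  db <- gen_signature_db(n_compounds = 40, n_genes = 300, n_reversers = 3,
                         query = query, strength = 3, seed = 21)
  res <- query_database(db$ranked, query)
  expect_equal(nrow(res), 40)
  expect_true(all(res$score >= -1 & res$score <= 1))
  expect_identical(res$rank, seq_len(40))
  # planted reversers occupy the most-reversing ranks
  expect_setequal(res$compound_id[1:3], db$truth$reversers)
  # batch scoring equals per-compound scoring
  single <- query_database(db$ranked[res$compound_id[5]], query)
  expect_equal(single$score, res$score[5])
  expect_equal(single$es_up, res$es_up[5])
  # swapping the query negates every score
  res_sw <- query_database(db$ranked, gene_set_pair(query$down, query$up))
  m <- match(res$compound_id, res_sw$compound_id)
  expect_equal(res_sw$score[m], -res$score)
})

test_that("random queries against random profiles score near zero on average", {
  set.seed(13)
  genes <- paste0("g", 1:200)
  scores <- replicate(200, {
    prof <- rank_profile(setNames(rnorm(200), genes))
    up <- sample(genes, 8)
    q <- gene_set_pair(up, sample(setdiff(genes, up), 8))
    eu <- enrichment_score(prof, q$up)$es
    ed <- enrichment_score(prof, q$down)$es
    connectivity_score(eu, ed)
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("the KS screen drops uniform profiles and keeps reversers", {
  query <- gene_set_pair(paste0("UP", 1:10), paste0("DN", 1:10))
  db <- gen_signature_db(n_compounds = 30, n_genes = 300, n_reversers = 2,
                         query = query, strength = 3, seed = 8)
  res <- query_database(db$ranked, query)
  kept <- suppressMessages(ks_filter(res, alpha = 0.05))
  expect_true(all(db$truth$reversers %in% kept$compound_id))
  expect_identical(suppressMessages(ks_filter(res, alpha = 1)), res)
  fake <- data.frame(compound_id = "x", ks_p = 0.5)
  expect_equal(nrow(suppressMessages(ks_filter(fake))), 0)
})

test_that("signature DB round-trips through TSV + manifest", {
  query <- gene_set_pair(paste0("UP", 1:5), paste0("DN", 1:5))
  db <- gen_signature_db(n_compounds = 6, n_genes = 50, n_reversers = 1,
                         query = query, strength = 3, seed = 4)
  genes <- names(db$profiles$values[[1]])
  M <- do.call(cbind, db$profiles$values)
  colnames(M) <- db$manifest$signature_id
  db_f <- tempfile(fileext = ".tsv"); man_f <- tempfile(fileext = ".csv")
  write.table(data.frame(gene = genes, M, check.names = FALSE), db_f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(db$manifest, man_f, row.names = FALSE)
  ranked <- read_signature_db(db_f, man_f)
  expect_setequal(names(ranked), unique(db$manifest$compound_id))
  r1 <- query_database(ranked, query)
  r2 <- query_database(db$ranked, query)
  m <- match(r1$compound_id, r2$compound_id)
  expect_equal(r1$score, r2$score[m], tolerance = 1e-12)
})
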
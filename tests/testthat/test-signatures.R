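test_that("log2 quantile normalization matches the hand-computed reference", {
  raw <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 32))
  rownames(raw) <- c("g1", "g2", "g3")
  out <- log2_quantile_normalize(raw)
  # sorted logs: (1,2,3) and (2,3,5); mean quantile target (1.5, 2.5, 4.0),
  # assigned by within-column rank (both columns are already sorted)
  expect_equal(unname(out[, 1]), c(1.5, 2.5, 4.0))
  expect_equal(unname(out[, 2]), c(1.5, 2.5, 4.0))
  # independent cross-check against limma on a larger random matrix
  m <- matrix(stats::rexp(200, 1 / 50) + 1, 40, 5)
  expect_equal(unname(log2_quantile_normalize(m)),
               unname(limma::normalizeQuantiles(log2(m), ties = TRUE)),
               ignore_attr = TRUE)
})

test_that("quantile normalization degenerate cases and idempotence", {
  one <- matrix(c(2, 8, 4), dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(log2_quantile_normalize(one)[, 1]), log2(c(2, 8, 4)))
  twin <- cbind(s1 = c(1, 3, 2), s2 = c(1, 3, 2))
  expect_equal(unname(log2_quantile_normalize(twin, already_logged = TRUE)),
               unname(twin), ignore_attr = TRUE)
  m <- matrix(stats::runif(60, 1, 100), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  once <- log2_quantile_normalize(m)
  twice <- log2_quantile_normalize(once, already_logged = TRUE)
  expect_identical(unname(once), unname(twice))
  # every column shares the same sorted value multiset
  sorted <- apply(once, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("non-positive values are rejected with the offending cell named", {
  m <- matrix(c(1, 2, -3, 4), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(log2_quantile_normalize(m), "gA.*s2|s2.*gA")
})

test_that("probe collapse keeps the max-mean probe and drops unmapped probes", {
  m <- rbind(p1 = c(5, 5), p2 = c(7, 7), p3 = c(1, 2), p4 = c(9, 9))
  colnames(m) <- c("s1", "s2")
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2")   # p4 unmapped
  out <- collapse_probes(m, map)
  expect_setequal(rownames(out), c("G1", "G2"))
  expect_equal(unname(out["G1", ]), c(7, 7))  # the mean-7 probe wins
  expect_equal(unname(out["G2", ]), c(1, 2))  # 1:1 mapping renames the row
  expect_error(collapse_probes(m, c(px = "G9")), "no probes mapped")
})

test_that("moderated t: null gene, label swap symmetry, limma cross-check", {
  set.seed(11)
  m <- matrix(rnorm(50 * 12, 8), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  m["g1", ] <- rep(c(1, 2, 3, 4, 5, 6), 2)   # case values == control values
  groups <- setNames(rep(c("case", "control"), each = 6), colnames(m))
  tab <- moderated_t_test(m, groups)
  expect_equal(tab$logFC[tab$gene == "g1"], 0)
  expect_equal(tab$p[tab$gene == "g1"], 1, tolerance = 1e-12)

  swapped <- setNames(ifelse(groups == "case", "control", "case"), names(groups))
  tab2 <- moderated_t_test(m, swapped)
  expect_equal(tab2$logFC, -tab$logFC)
  expect_equal(tab2$p, tab$p)

  # full limma pipeline as independent oracle
  design <- cbind(Intercept = 1, case = as.numeric(groups == "case"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(tab$logFC, unname(fit$coefficients[, "case"]), tolerance = 1e-10)
  expect_equal(tab$t, unname(fit$t[, "case"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[, "case"]), tolerance = 1e-8)

  expect_error(moderated_t_test(m[, 1:7],
                                setNames(c("case", rep("control", 6)),
                                         colnames(m)[1:7])),
               ">= 2 samples")
})

test_that("prior df 0 reduces the moderated t to the ordinary two-sample t", {
  set.seed(3)
  m <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  groups <- setNames(rep(c("case", "control"), each = 3), colnames(m))
  tab <- moderated_t_test(m, groups, prior_df = 0)
  for (g in rownames(m)) {
    t_ref <- ordinary_t_oracle(m[g, 1:3], m[g, 4:6])
    expect_equal(tab$t[tab$gene == g], t_ref, tolerance = 1e-12)
  }
  # and agrees with stats::t.test pooled variance p-values
  tt <- stats::t.test(m[1, 1:3], m[1, 4:6], var.equal = TRUE)
  expect_equal(tab$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("DEG filtering applies strict thresholds", {
  tab <- data.frame(
    gene = paste0("g", 1:5),
    logFC = c(0.5, 0.5, -1.2, 0.0, 2.0),
    t = 0, p = c(0.04, 0.05, 0.01, 0.001, 0.2), p_adj_BH = NA)
  pair <- suppressMessages(filter_degs(tab, p_thresh = 0.05, lfc_thresh = 0))
  expect_setequal(pair$up, c("g1"))        # g2 fails p (strict), g4 fails lfc,
  expect_setequal(pair$down, c("g3"))      # g5 fails p
  pair2 <- filter_degs(tab, p_thresh = 0.21, lfc_thresh = 0)
  expect_setequal(pair2$up, c("g1", "g2", "g5"))
})

test_that("signature intersection is order-invariant, associative, and drops conflicts", {
  a <- gene_set_pair(c("u1", "u2", "u3"), c("d1", "d2"))
  b <- gene_set_pair(c("u2", "u3", "u4"), c("d2", "d3"))
  c3 <- gene_set_pair(c("u3", "u2", "u9"), c("d2", "d9"))
  expect_identical(intersect_signatures(list(a)), structure(
    list(up = sort(a$up), down = sort(a$down)), class = "gene_set_pair"))
  r1 <- intersect_signatures(list(a, b, c3))
  r2 <- intersect_signatures(list(c3, b, a))
  expect_identical(r1, r2)
  nested <- intersect_signatures(list(intersect_signatures(list(a, b)), c3))
  expect_identical(r1, nested)
  expect_setequal(r1$up, c("u2", "u3"))
  expect_setequal(r1$down, "d2")
  # disjoint up sets intersect to empty
  d <- gene_set_pair("x1", "y1")
  expect_length(intersect_signatures(list(a, d))$up, 0)
  # the sign-conflict guard: a gene cannot survive in both directions
  # (constructed on raw pairs, since validated pairs are direction-disjoint)
  e1 <- list(up = c("g", "z"), down = c("z", "q"))
  e2 <- list(up = c("g", "z"), down = c("z", "q"))
  expect_message(res <- intersect_signatures(list(e1, e2)), "conflict")
  expect_false("z" %in% res$up || "z" %in% res$down)
  expect_setequal(res$up, "g")
})

test_that("planted DE genes are recovered across intersected synthetic cohorts", {
  sim <- gen_cohorts(n_genes = 800, n_case = 10, n_control = 10, n_de = 60,
                     effect = 2, sigma = 0.5, n_cohorts = 3, seed = 42)
  pairs <- lapply(sim$cohorts, function(co)
    filter_degs(moderated_t_test(co$matrix, co$groups)))
  sig <- intersect_signatures(pairs)
  recovered <- c(sig$up, sig$down)
  recall <- mean(sim$truth$de_genes %in% recovered)
  expect_gte(recall, 0.9)
  expect_true(all(sig$up %in% sim$truth$up_genes))
  expect_true(all(sig$down %in% sim$truth$down_genes))
})

test_that("GRP / GMT / DEG table round trips", {
  pair <- gene_set_pair(c("A", "B"), c("C"))
  up_f <- tempfile(fileext = ".grp"); gmt_f <- tempfile(fileext = ".gmt")
  write_grp(pair$up, up_f)
  expect_identical(read_grp(up_f), c("A", "B"))
  write_gmt(pair, gmt_f, name = "IS")
  rt <- read_gmt_pair(gmt_f)
  expect_identical(rt$up, pair$up)
  expect_identical(rt$down, pair$down)

  tab <- data.frame(gene = c("A", "B"), logFC = c(1, -2), t = c(2, -3),
                    p = c(0.01, 0.02), p_adj_BH = c(0.02, 0.02))
  out_f <- tempfile(fileext = ".tsv")
  write_deg_table(tab, out_f)
  rt2 <- utils::read.delim(out_f)
  expect_identical(rt2$direction, c("up", "down"))
})

test_that("expression TSV and GCT loaders agree", {
  m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression_tsv(tsv), m, ignore_attr = TRUE)
  gct <- tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t2",
               paste(c("NAME", "Description", "s1", "s2"), collapse = "\t"),
               sapply(1:3, function(i)
                 paste(c(rownames(m)[i], "na", m[i, ]), collapse = "\t"))), gct)
  g <- read_gct(gct)
  expect_equal(g, m, ignore_attr = TRUE)
})
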
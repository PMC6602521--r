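dgeTab <- function(gene_id, log2fc, pvalue, padj = NA_real_) {
    data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
               padj = padj, stringsAsFactors = FALSE)
}

test_that("DE ranking filters by direction then ranks by p-value", {
    d <- dgeTab(c("gA", "gB"), c(1, -1), c(1e-8, 0.5))
    expect_equal(rankByDE(d)$rank, c(1, 2))
    d2 <- dgeTab(c("gA", "gB"), c(2, -2), c(0.9, 1e-9))
    up <- rankByDE(d2, "up")
    expect_equal(up$gene_id, "gA")  # gB excluded despite smaller p
    expect_equal(up$rank, 1)
    down <- rankByDE(d2, "down")
    expect_equal(down$gene_id, "gB")
    tied <- rankByDE(dgeTab(c("gB", "gA"), c(1, 1), c(0.2, 0.2)))
    expect_equal(tied$rank, c(1.5, 1.5))
    expect_equal(tied$gene_id, c("gA", "gB"))
    expect_error(rankByDE(dgeTab("gA", -1, 0.1), "up"), "up")
})

test_that("rank product multiplies re-computed ranks on the intersection", {
    rp <- rankByAdjustedRP(c(gA = 0.9, gB = 0.7, gC = 0.5, gD = 0.3,
                             gE = 0.1))
    de <- rankByDE(dgeTab(c("gA", "gB", "gC", "gD", "gE"), 1,
                          c(0.5, 0.01, 0.2, 0.3, 0.4)))
    ens <- rankProduct(rp, de)
    # gC: RP rank 3, DE rank 2 -> product 6; check one by hand fully
    expect_equal(ens$rank_product[ens$gene_id == "gC"], 3 * 2)
    expect_equal(ens$rank_product,
                 ens$rank_rp * ens$rank_de)
    # a gene ranked 1 in both is necessarily final rank 1
    rp2 <- rankByAdjustedRP(c(gA = 1, gB = 0.5, gC = 0.2))
    de2 <- rankByDE(dgeTab(c("gA", "gB", "gC"), 1, c(1e-6, 0.5, 0.9)))
    ens2 <- rankProduct(rp2, de2)
    expect_equal(ens2$gene_id[ens2$final_rank == 1], "gA")
    expect_equal(ens2$rank_product[1], 1)
})

test_that("rank product drops non-shared genes with re-ranking", {
    rp <- rankByAdjustedRP(c(gA = 0.9, gB = 0.5, gC = 0.1))
    de <- rankByDE(dgeTab(c("gB", "gC", "gD"), 1, c(0.1, 0.2, 0.3)))
    expect_message(ens <- rankProduct(rp, de), "dropped 1 binding-only")
    expect_setequal(ens$gene_id, c("gB", "gC"))
    # ranks recomputed within {gB, gC}: both scales are 1..2
    expect_setequal(ens$rank_rp, c(1, 2))
    expect_setequal(ens$rank_de, c(1, 2))
    rpX <- rankByAdjustedRP(c(gX = 1))
    expect_error(rankProduct(rpX, de), "empty intersection")
})

test_that("rank product is symmetric and monotone in DE improvement", {
    set.seed(31)
    ids <- sprintf("g%02d", 1:40)
    rp <- rankByAdjustedRP(stats::setNames(runif(40), ids))
    pv <- runif(40)
    de <- rankByDE(dgeTab(ids, 1, pv))
    a <- rankProduct(rp, de)
    b <- rankProduct(de, rp)  # swapped inputs
    b <- b[match(a$gene_id, b$gene_id), ]
    expect_equal(a$rank_product, b$rank_product)
    expect_equal(a$final_rank, b$final_rank)
    # strictly improving one gene's p-value never worsens its final rank
    g <- ids[17]
    pv2 <- pv; pv2[17] <- pv[17] / 10
    a2 <- rankProduct(rp, rankByDE(dgeTab(ids, 1, pv2)))
    expect_lte(a2$final_rank[a2$gene_id == g],
               a$final_rank[a$gene_id == g])
})

test_that("ROC/PR handle perfect, inverted and random orderings", {
    adj <- c(gA = 0.9, gB = 0.8, gC = 0.2, gD = 0.1)
    pos2 <- dgeTab(names(adj), 1, c(1e-4, 1e-4, 0.9, 0.9),
                   c(1e-3, 1e-3, 0.95, 0.95))
    cv <- bindingExpressionCurves(adj, pos2)
    expect_equal(cv$auroc, 1)
    expect_equal(cv$roc$fpr[1], 0); expect_equal(cv$roc$tpr[1], 0)
    expect_equal(utils::tail(cv$roc$fpr, 1), 1)
    expect_equal(utils::tail(cv$roc$tpr, 1), 1)
    expect_equal(cv$aupr, 1)
    two <- c(gA = 0.1, gB = 0.9)
    anti <- dgeTab(names(two), 1, c(1e-4, 0.9), c(1e-3, 0.95))
    expect_equal(bindingExpressionCurves(two, anti)$auroc, 0)
    allpos <- dgeTab(names(two), 1, c(1e-4, 1e-4), c(1e-3, 1e-3))
    expect_error(bindingExpressionCurves(two, allpos), "positive")
})

test_that("trapezoid AUROC equals the Mann-Whitney statistic", {
    set.seed(17)
    for (i in 1:10) {
        n <- 200
        ids <- sprintf("g%03d", seq_len(n))
        adj <- stats::setNames(round(rnorm(n), 1), ids)  # forces ties
        labels <- runif(n) < 0.3
        labels[1] <- TRUE; labels[2] <- FALSE
        d <- dgeTab(ids, 1, ifelse(labels, 1e-6, 0.9),
                    ifelse(labels, 1e-4, 0.95))
        cv <- bindingExpressionCurves(adj, d)
        u <- wilcox.test(adj[labels], adj[!labels],
                         exact = FALSE)$statistic
        expect_equal(cv$auroc, unname(u) / (sum(labels) * sum(!labels)),
                     tolerance = 1e-12)
    }
})

test_that("random scores against independent labels give AUROC ~ 0.5", {
    set.seed(19)
    n <- 10000
    ids <- sprintf("g%05d", seq_len(n))
    adj <- stats::setNames(rnorm(n), ids)
    labels <- runif(n) < 0.5
    d <- dgeTab(ids, 1, ifelse(labels, 1e-6, 0.9),
                ifelse(labels, 1e-4, 0.95))
    expect_equal(bindingExpressionCurves(adj, d)$auroc, 0.5,
                 tolerance = 0.04)  # |auroc - 0.5| <= 0.02
})

test_that("direction restricts the positive labels of the curves", {
    set.seed(23)
    n <- 48
    ids <- sprintf("g%02d", seq_len(n))
    adj <- stats::setNames(runif(n), ids)
    lfc <- rep(c(2, -2), n / 2)
    d <- dgeTab(ids, lfc, rep(c(1e-5, 1e-5, 0.9, 0.9), n / 4),
                rep(c(1e-3, 1e-3, 0.95, 0.95), n / 4))
    both <- bindingExpressionCurves(adj, d)
    up <- bindingExpressionCurves(adj, d, direction = "up")
    expect_equal(up$n_pos * 2, both$n_pos)
})
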
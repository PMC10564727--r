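test_that("generation is deterministic and respects the declared types", {
    panel <- fxSmallPanel()
    panel2 <- generateDevelopmentPanel(panel$config)
    expect_identical(assay(panel$datasets[[1]], "counts"),
                     assay(panel2$datasets[[1]], "counts"))
    expect_identical(as.data.frame(colData(panel$datasets[[2]])),
                     as.data.frame(colData(panel2$datasets[[2]])))
    # private type only in its species
    t1 <- colData(panel$datasets$species1)$true_type
    t2 <- colData(panel$datasets$species2)$true_type
    expect_true("Goblet" %in% t1)
    expect_false("Goblet" %in% t2)
    # every non-control dataset has AER cells
    expect_true(all(vapply(panel$datasets, function(d)
        "AER" %in% colData(d)$true_type, TRUE)))
})

test_that("negative-control dataset contains no AER cells", {
    cfg <- synthConfig(nSpecies = 2, cellsPerDataset = 100, nGenes = 500,
                       sharedTypes = c(AER = 0.2, CT = 0.4, Muscle = 0.4),
                       privateTypes = list(), nPrivateGenes = 0,
                       negativeControl = TRUE, negativeControlSpecies = 2,
                       transcriptDupSpecies = 0, seed = 7)
    panel <- generateDevelopmentPanel(cfg)
    expect_false("AER" %in% colData(panel$datasets[[2]])$true_type)
    expect_true("AER" %in% colData(panel$datasets[[1]])$true_type)
})

test_that("too few cells for the declared types is an error naming the shortfall", {
    cfg <- synthConfig(nSpecies = 1, cellsPerDataset = 2, nGenes = 500,
                       sharedTypes = c(AER = 0.2, CT = 0.4, Muscle = 0.4),
                       privateTypes = list(), nPrivateGenes = 0,
                       transcriptDupSpecies = 0)
    expect_error(generateDevelopmentPanel(cfg), "short by")
})

test_that("mean depth per cell stays within 10% of depthMean", {
    cfg <- synthConfig(nSpecies = 1, cellsPerDataset = 500, nGenes = 600,
                       sharedTypes = c(AER = 0.2, CT = 0.4, Muscle = 0.4),
                       privateTypes = list(), nPrivateGenes = 0,
                       transcriptDupSpecies = 0, depthMean = 4000, seed = 3)
    panel <- generateDevelopmentPanel(cfg)
    depth <- mean(colSums(assay(panel$datasets[[1]], "counts")))
    expect_lt(abs(depth - 4000) / 4000, 0.1)
})

test_that("program placement follows the internal mean profiles", {
    panel <- fxSmallPanel()
    u <- panel$genes
    prof <- panel$profiles
    base <- prof["CT", ]  # CT carries no program genes
    prog <- u$symbols[u$program]
    expect_true(all(prof["AER", prog] > base[prog]))
    # AEC elevates exactly the overlap subset
    n_ov <- ceiling(panel$config$aecOverlap * length(prog))
    elevated <- prof["AEC", prog] > base[prog]
    expect_identical(unname(which(elevated)), seq_len(n_ov))
    # non-program background genes identical across AER and CT
    bg <- setdiff(u$symbols, c(prog, u$symbols[unlist(u$markers)],
                               u$symbols[c(u$cycleS, u$cycleG2M)]))
    expect_equal(prof["AER", bg], prof["CT", bg])
})

test_that("regeneration carrier flagging is exact and respects zero fraction", {
    # CT share is 0.40, so 1250 cells give 500 CT cells and 150 carriers
    cfg <- synthConfig(nSpecies = 1, cellsPerDataset = 1250, nGenes = 500,
                       privateTypes = list(), nPrivateGenes = 0,
                       transcriptDupSpecies = 0, ctProgramFraction = 0.3,
                       timepoints = "3dpa", seed = 7)
    regen <- generateRegenerationSeries(cfg)
    cd <- colData(regen$datasets[[1]])
    ct <- cd$true_type == "CT"
    expect_identical(sum(ct), 500L)
    expect_identical(sum(cd$carries_program & ct), as.integer(round(0.3 * 500)))
    cfg0 <- synthConfig(nSpecies = 1, cellsPerDataset = 200, nGenes = 500,
                        privateTypes = list(), nPrivateGenes = 0,
                        transcriptDupSpecies = 0, ctProgramFraction = 0,
                        timepoints = "3dpa", seed = 7)
    regen0 <- generateRegenerationSeries(cfg0)
    cd0 <- colData(regen0$datasets[[1]])
    expect_false(any(cd0$carries_program & cd0$true_type == "CT"))
})

test_that("without a planted cycle no PC correlates with the cycling flag", {
    cfg <- synthConfig(nSpecies = 1, cellsPerDataset = 300, nGenes = 500,
                       sharedTypes = c(AER = 0.2, CT = 0.4, Muscle = 0.4),
                       privateTypes = list(), nPrivateGenes = 0,
                       transcriptDupSpecies = 0, cycleStrength = 0, seed = 7)
    panel <- generateDevelopmentPanel(cfg)
    d <- normalizeSelectHVG(panel$datasets[[1]], nHVG = 300)
    pca <- fitPCA(d, nComponents = 20)
    cors <- abs(cor(pcaScores(pca), colData(d)$cycling))
    expect_lt(max(cors), 0.3)
})

test_that("spatial section has one domain per spot and summed spot counts", {
    cfg <- synthConfig(nSpecies = 1, privateTypes = list(), nPrivateGenes = 0,
                       transcriptDupSpecies = 0, gridNrow = 20, gridNcol = 20,
                       seed = 7)
    sec <- generateSpatialSection(cfg)
    expect_identical(ncol(sec$spots), 400L)
    expect_identical(sort(unique(colData(sec$spots)$domain)),
                     c("AEC_rim", "blastema", "intact_CT"))
    # construction rule: spot counts are column sums of constituent cells
    spot <- colnames(sec$spots)[5]
    members <- colData(sec$cells)$spot_id == spot
    expect_equal(unname(assay(sec$spots, "counts")[, spot]),
                 unname(rowSums(assay(sec$cells, "counts")[, members,
                                                           drop = FALSE])))
    # AEC rim has higher mean program expression than intact CT
    prog <- limbatlas:::.gene_universe(sec$config)
    pg <- intersect(prog$symbols[prog$program], rownames(sec$spots))
    logc <- logNorm(sec$spots)
    pm <- colMeans(logc[pg, ])
    dom <- colData(sec$spots)$domain
    expect_gt(mean(pm[dom == "AEC_rim"]), mean(pm[dom == "intact_CT"]))
    # grid too small
    expect_error(generateSpatialSection(
        synthConfig(nSpecies = 1, privateTypes = list(), nPrivateGenes = 0,
                    transcriptDupSpecies = 0, gridNrow = 2, gridNcol = 4)),
        "too small")
})

test_that("panel round-trips through the on-disk text formats", {
    panel <- fxSmallPanel()
    dir <- tempfile("panel")
    writePanel(panel, dir)
    back <- readCountsMTX(file.path(dir, "species1"), species = "species1")
    expect_equal(as.matrix(assay(back, "counts")),
                 as.matrix(assay(panel$datasets$species1, "counts")))
    orth <- readOrthology(file.path(dir, "orthology.tsv"))
    expect_identical(nrow(orth), nrow(panel$orthology))
    cfg2 <- readSynthConfig(file.path(dir, "config.yaml"))
    expect_equal(cfg2$nGenes, panel$config$nGenes)
    expect_equal(cfg2$sharedTypes, panel$config$sharedTypes)
    unlink(dir, recursive = TRUE)
})
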
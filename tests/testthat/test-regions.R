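test_that("interface residues map to alignment columns by direct lookup", {
  aln <- mkAln("famX", "d1", nRes = 20)
  i <- mkIface("IF_1", "d1", c(10, 12))
  m <- mapInterfaceToColumns(i, aln)
  expect_equal(m$columns, c(9L, 11L))      # 0-based internally
  expect_equal(m$unmapped, 0L)
  # residue absent from the map is dropped and counted
  i2 <- mkIface("IF_2", "d1", c(10, 99))
  m2 <- mapInterfaceToColumns(i2, aln)
  expect_equal(m2$columns, 9L)
  expect_equal(m2$unmapped, 1L)
  expect_error(mapInterfaceToColumns(mkIface("IF_3", "nope", 1), aln),
               "nope")
})

test_that("region similarity is overlap over the smaller set", {
  expect_equal(regionSimilarity(1:3, 2:4), 2 / 3)
  expect_equal(regionSimilarity(1:3, 1:3), 1.0)
  expect_equal(regionSimilarity(1:3, 7:9), 0.0)
  expect_equal(regionSimilarity(integer(), integer()), 0.0)
  # containment scores 1 regardless of size difference
  expect_equal(regionSimilarity(1:2, 1:10), 1.0)
})

test_that("single-linkage clustering over the similarity graph", {
  aln <- mkAln("famX", c("d1", "d2", "d3"), nRes = 30)
  # sims: (i1,i2) = 2/4 = 0.5; i3 disjoint from both
  i1 <- mkIface("IF_1", "d1", 1:4)
  i2 <- mkIface("IF_2", "d2", 3:6)
  i3 <- mkIface("IF_3", "d3", 20:21)
  cl0 <- clusterRegions(list(i1, i2, i3), aln, cutoff = 0)
  expect_length(cl0$regions, 2L)
  cl6 <- clusterRegions(list(i1, i2, i3), aln, cutoff = 0.6)
  expect_length(cl6$regions, 3L)           # 0.5 edge does not survive 0.6
  # identical interfaces always cluster below similarity 1
  clId <- clusterRegions(list(mkIface("IF_1", "d1", 1:4),
                              mkIface("IF_2", "d2", 1:4)), aln,
                         cutoff = 0.99)
  expect_length(clId$regions, 1L)
  # region column set is the union of member column sets
  r <- cl0$regions[[1]]
  expect_equal(columnSet(r), 0:5)
  expect_equal(regionId(r), "BR_1")
  # interface not in the alignment is excluded and reported
  expect_warning(
    clX <- clusterRegions(list(i1, mkIface("IF_9", "dZ", 1:3)), aln),
    "excluded")
  expect_equal(clX$excluded, "IF_9")
})

test_that("clustering equals a brute-force transitive-closure oracle", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(4:12, 1)
    members <- paste0("d", seq_len(n))
    aln <- mkAln("famX", members, nRes = 15)
    ifaces <- lapply(seq_len(n), function(k)
      mkIface(sprintf("IF_%02d", k), members[k],
              sort(sample(1:15, sample(2:6, 1)))))
    for (cutoff in c(0, 0.3, 0.7)) {
      got <- clusterRegions(ifaces, aln, cutoff = cutoff)
      colSets <- lapply(ifaces, function(i)
        mapInterfaceToColumns(i, aln)$columns)
      oracle <- transitiveClosureClusters(colSets, cutoff)
      expect_equal(length(got$regions), length(unique(oracle)))
      # identical partition, not just the same count
      gotLab <- integer(n)
      for (k in seq_along(got$regions))
        gotLab[match(interfaceIds(got$regions[[k]]),
                     vapply(ifaces, interfaceId, ""))] <- k
      canon <- function(lab) match(lab, unique(lab))
      expect_equal(canon(gotLab), canon(oracle))
    }
  }
})

test_that("region count is non-decreasing in the clustering cutoff", {
  set.seed(5)
  members <- paste0("d", 1:8)
  aln <- mkAln("famX", members, nRes = 12)
  ifaces <- lapply(1:8, function(k)
    mkIface(sprintf("IF_%02d", k), members[k],
            sort(sample(1:12, sample(3:7, 1)))))
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(cut)
    length(clusterRegions(ifaces, aln, cutoff = cut)$regions), 1L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], 8L)   # cutoff 1: all singletons
})

test_that("hierarchy groups interfaces by ligand and is deterministic", {
  aln <- mkAln("famX", c("d1", "d2"), nRes = 20)
  i1 <- mkIface("IF_1", "d1", 5:9, ligType = "dna", lig = "na1")
  i2 <- mkIface("IF_2", "d2", 5:9, ligType = "protein", lig = "d1")
  cl <- clusterRegions(list(i1, i2), aln, cutoff = 0)
  expect_length(cl$regions, 1L)
  h <- assembleHierarchy(cl$regions, list(i1, i2), cutoff = 0)
  fam <- hierarchyFamilies(h)[["famX"]]
  expect_length(fam$regions, 1L)
  expect_length(fam$regions[[1]]$ifGroups, 2L)   # one DNA group, one protein
  expect_setequal(vapply(fam$regions[[1]]$ifGroups, function(g)
    g$ligandType, ""), c("dna", "protein"))
  # columns are reported 1-based
  expect_equal(fam$regions[[1]]$columns, 5:9)

  # byte-identical output regardless of interface input order
  h2 <- assembleHierarchy(clusterRegions(list(i2, i1), aln, 0)$regions,
                          list(i2, i1), cutoff = 0)
  f1 <- tempfile(); f2 <- tempfile()
  writeHierarchy(h, f1); writeHierarchy(h2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("search filters implement conjunctive ligand selection", {
  aln <- mkAln("famX", c("d1", "d2", "d3"), nRes = 30)
  # region 1 binds dna + protein; region 2 binds protein only
  i1 <- mkIface("IF_1", "d1", 1:5, ligType = "dna", lig = "na1")
  i2 <- mkIface("IF_2", "d2", 1:5, ligType = "protein", lig = "dX")
  i3 <- mkIface("IF_3", "d3", 20:25, ligType = "protein", lig = "dY")
  cl <- clusterRegions(list(i1, i2, i3), aln, cutoff = 0)
  h <- assembleHierarchy(cl$regions, list(i1, i2, i3), cutoff = 0)
  expect_length(hierarchyFamilies(h)[["famX"]]$regions, 2L)

  both <- applySearchFilters(h, ligandTypeFilter(c("protein", "dna")))
  regs <- hierarchyFamilies(both)[["famX"]]$regions
  expect_length(regs, 1L)                       # protein-only region dropped
  expect_setequal(vapply(regs[[1]]$ifGroups, function(g) g$ligandType, ""),
                  c("dna", "protein"))

  # hetero filter on a homo-only region drops the region
  hHomo <- assembleHierarchy(
    clusterRegions(list(mkIface("IF_1", "d1", 1:5,
                                complexClass = "homo")), aln, 0)$regions,
    list(mkIface("IF_1", "d1", 1:5, complexClass = "homo")), cutoff = 0)
  expect_length(hierarchyFamilies(
    applySearchFilters(hHomo, ligandTypeFilter(complexType = "hetero"))), 0L)

  # any/any/any leaves the hierarchy unchanged
  same <- applySearchFilters(h, ligandTypeFilter())
  f1 <- tempfile(); f2 <- tempfile()
  writeHierarchy(h, f1); writeHierarchy(same, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(ligandTypeFilter("sugar"), "unknown ligand type")
})

test_that("every interface lands in exactly one region or the exclusion report", {
  set.seed(23)
  members <- paste0("d", 1:6)
  aln <- mkAln("famX", members, nRes = 10)
  ifaces <- c(lapply(1:6, function(k)
    mkIface(sprintf("IF_%02d", k), members[k],
            sort(sample(1:10, 3)))),
    list(mkIface("IF_99", "dAlien", 1:3)))
  expect_warning(cl <- clusterRegions(ifaces, aln, cutoff = 0.4))
  inRegions <- unlist(lapply(cl$regions, interfaceIds))
  expect_equal(sort(c(inRegions, cl$excluded)),
               sort(vapply(ifaces, interfaceId, "")))
  expect_false(anyDuplicated(inRegions) > 0)
})
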
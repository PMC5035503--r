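## Shared simulated populations, built once per test run and cached.
## Sizes are desk-scale stand-ins for the three-density sheep design:
## panels of ~10% / 50% / 100% of the frame mirror the 5K in 50K in HD
## nesting, divergences mirror closely related dual-purpose breeds plus a
## weakly connected terminal group.

.worlds <- new.env(parent = emptyenv())

.world <- function(name, builder) {
  if (is.null(.worlds[[name]])) .worlds[[name]] <- builder()
  .worlds[[name]]
}

## Multi-breed world (~525 animals x 1000 SNPs) for relatedness, scenario
## and predictor tests.
worldMulti <- function() .world("multi", function() {
  pop <- simulatePopulation(defaultBreedPlan(), defaultGeneticMap(4L, 250L),
                            seed = 20260901)
  tab <- pedigreeTable(pop$pedigree)
  panels <- nestedPanels(pop$truth, c(low = 100L, mid = 500L, high = NA))
  rom <- tab$id[tab$romney == 1]
  lastYear <- max(tab$year)
  romYoung <- rom[tab$year[match(rom, tab$id)] == lastYear]
  terminal <- tab$id[tab$terminal == 1 & tab$year == lastYear]
  list(pop = pop, tab = tab, panels = panels,
       romTargets = head(romYoung, 30L),
       romRefs = setdiff(rom, head(romYoung, 30L)),
       termTargets = head(terminal, 15L))
})

## Larger multi-breed world (~1050 animals x 2000 SNPs) for the directional
## scenario properties.
worldScenario <- function() .world("scenario", function() {
  pop <- simulatePopulation(defaultBreedPlan(scale = 2), defaultGeneticMap(4L, 500L),
                            seed = 20260902)
  tab <- pedigreeTable(pop$pedigree)
  panels <- nestedPanels(pop$truth, c(low = 200L, mid = 1000L, high = NA))
  rom <- tab$id[tab$romney == 1]
  lastYear <- max(tab$year)
  romYoung <- rom[tab$year[match(rom, tab$id)] == lastYear]
  terminal <- tab$id[tab$terminal == 1 & tab$year == lastYear]
  targets <- head(romYoung, 60L)
  list(pop = pop, tab = tab, panels = panels, targets = targets,
       refs = setdiff(rom, targets), termTargets = head(terminal, 25L))
})

## Single-breed world at 10,000 SNPs for pedigree-expectation checks
## (parent-offspring G near 0.5 needs many SNPs).
worldSingleBreed <- function() .world("single", function() {
  plan <- BreedPlan(
    breeds = "romney", divergence = c(romney = 0.05),
    founders = c(romney = 40L),
    matings = list(
      list(list(dam = c(romney = 1), sire = c(romney = 1), n = 60L)),
      list(list(dam = c(romney = 1), sire = c(romney = 1), n = 60L))))
  pop <- simulatePopulation(plan, defaultGeneticMap(5L, 2000L), seed = 20260903)
  list(pop = pop, tab = pedigreeTable(pop$pedigree))
})

## Two-breed world (2000 SNPs, ~300 animals) for the baseline closed form.
worldTwoBreed <- function() .world("two", function() {
  plan <- BreedPlan(
    breeds = c("romney", "coopworth"),
    divergence = c(romney = 0.05, coopworth = 0.08),
    founders = c(romney = 40L, coopworth = 40L),
    matings = list(
      list(list(dam = c(romney = 1, coopworth = 0),
                sire = c(romney = 1, coopworth = 0), n = 60L),
           list(dam = c(romney = 0, coopworth = 1),
                sire = c(romney = 0, coopworth = 1), n = 50L)),
      list(list(dam = c(romney = 1, coopworth = 0),
                sire = c(romney = 1, coopworth = 0), n = 60L),
           list(dam = c(romney = 0, coopworth = 1),
                sire = c(romney = 0, coopworth = 1), n = 50L))))
  pop <- simulatePopulation(plan, defaultGeneticMap(4L, 500L), seed = 20260904)
  list(pop = pop, tab = pedigreeTable(pop$pedigree))
})

## Large within-breed world for per-SNP r2 (rare-allele workflow wants a
## large imputed set; >= 1000 targets).
worldRare <- function() .world("rare", function() {
  plan <- BreedPlan(
    breeds = "romney", divergence = c(romney = 0.05),
    founders = c(romney = 80L),
    matings = list(
      list(list(dam = c(romney = 1), sire = c(romney = 1), n = 700L)),
      list(list(dam = c(romney = 1), sire = c(romney = 1), n = 1000L)),
      list(list(dam = c(romney = 1), sire = c(romney = 1), n = 1100L))))
  pop <- simulatePopulation(plan, defaultGeneticMap(4L, 500L), seed = 20260905)
  tab <- pedigreeTable(pop$pedigree)
  panels <- nestedPanels(pop$truth, c(low = 200L, high = NA))
  lastYear <- max(tab$year)
  targets <- head(tab$id[tab$year == lastYear], 1000L)
  list(pop = pop, tab = tab, panels = panels, targets = targets,
       refs = setdiff(tab$id, targets))
})
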
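{
  "version": 1,
  "units": "pixels (0.46 um/px scale metadata); intensities in optical density",
  "features": [
    "Area", "Perimeter", "MajorAxisLength", "MinorAxisLength",
    "MinorMajorRatio", "MinFeretDiameter", "MaxFeretDiameter",
    "Eccentricity", "Solidity", "Extent", "FormFactor", "Compactness",
    "EquivalentDiameter",
    "IntensityMean", "IntensitySD", "IntensityMin", "IntensityMax",
    "IntensityMedian", "IntensityMAD",
    "AngularSecondMoment", "Contrast", "Correlation", "SumOfSquaresVariance",
    "InverseDifferenceMoment", "SumAverage", "SumVariance", "SumEntropy",
    "Entropy", "DifferenceVariance", "DifferenceEntropy",
    "InfoMeasureCorrelation1", "InfoMeasureCorrelation2"
  ]
}
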
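<?xml version="1.0" encoding="UTF-8"?>
<!-- Smallest useful model: uptake plus sink for one metabolite.  The sink
     is declared "irreversible backward" (bounds [-1000, 0]), so the loader
     must re-orient its column.  The notes-style GENE_ASSOCIATION fallback
     is exercised on the uptake reaction. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="minimal_backward">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="M_ext" compartment="c" constant="false" boundaryCondition="true" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_back" value="-1000" constant="true"/>
      <parameter id="ub_zero" value="0" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_free" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="uptake" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: gU1 or gU2</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="M_ext" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="sink" reversible="true" fast="false" fbc:lowerFluxBound="lb_back" fbc:upperFluxBound="ub_zero">
        <listOfProducts>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
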
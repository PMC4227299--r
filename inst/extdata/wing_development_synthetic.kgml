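<?xml version="1.0" encoding="UTF-8"?>
<!-- Hand-constructed synthetic template of an insect wing-development
     regulatory pathway (selector and signalling genes of the wing
     imaginal disc). The K numbers are synthetic placeholders, not KEGG
     assignments; the topology is a conventional textbook wiring used
     here as a projection/round-trip test asset. -->
<pathway name="path:ko99001" org="ko" number="99001"
         title="Wing development (synthetic template)">
  <entry id="1" name="ko:K95001" type="ortholog">
    <graphics name="en" type="rectangle" x="100" y="60" width="46" height="17"/>
  </entry>
  <entry id="2" name="ko:K95002" type="ortholog">
    <graphics name="hh" type="rectangle" x="180" y="60" width="46" height="17"/>
  </entry>
  <entry id="3" name="ko:K95003" type="ortholog">
    <graphics name="dpp" type="rectangle" x="260" y="60" width="46" height="17"/>
  </entry>
  <entry id="4" name="ko:K95004" type="ortholog">
    <graphics name="sal" type="rectangle" x="340" y="60" width="46" height="17"/>
  </entry>
  <entry id="5" name="ko:K95005" type="ortholog">
    <graphics name="Ubx" type="rectangle" x="260" y="140" width="46" height="17"/>
  </entry>
  <entry id="6" name="ko:K95006" type="ortholog">
    <graphics name="vg" type="rectangle" x="420" y="100" width="46" height="17"/>
  </entry>
  <entry id="7" name="ko:K95007" type="ortholog">
    <graphics name="hth" type="rectangle" x="420" y="180" width="46" height="17"/>
  </entry>
  <entry id="8" name="ko:K95008" type="ortholog">
    <graphics name="ap" type="rectangle" x="100" y="220" width="46" height="17"/>
  </entry>
  <entry id="9" name="ko:K95009" type="ortholog">
    <graphics name="Ser" type="rectangle" x="180" y="220" width="46" height="17"/>
  </entry>
  <entry id="10" name="ko:K95010" type="ortholog">
    <graphics name="wg" type="rectangle" x="260" y="220" width="46" height="17"/>
  </entry>
  <entry id="11" name="ko:K95011" type="ortholog">
    <graphics name="Dll" type="rectangle" x="340" y="260" width="46" height="17"/>
  </entry>
  <entry id="12" name="ko:K95012" type="ortholog">
    <graphics name="ac/sc" type="rectangle" x="340" y="300" width="46" height="17"/>
  </entry>
  <entry id="13" name="path:ko99002" type="map">
    <graphics name="Hormone signalling" type="roundrectangle" x="520" y="60" width="110" height="34"/>
  </entry>
  <entry id="14" name="cpd:C00000" type="compound">
    <graphics name="morphogen" type="circle" x="520" y="140" width="8" height="8"/>
  </entry>
  <relation entry1="1" entry2="2" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="3" entry2="4" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="5" entry2="3" type="GErel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="8" entry2="9" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="9" entry2="10" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="10" entry2="6" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="10" entry2="11" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="7" entry2="6" type="GErel">
    <subtype name="inhibition" value="--|"/>
  </relation>
  <relation entry1="6" entry2="12" type="GErel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
</pathway>
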
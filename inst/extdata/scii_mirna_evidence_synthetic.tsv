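mirna	dataset	direction	method
rno-let-7f-5p	LY2018	down	literature
rno-miR-105	ZGL2020	up	literature
rno-miR-1188-3p	LJA2016	down	literature
rno-miR-125b-2-3p	WXY2019	down	literature
rno-miR-125b-5p	HJR2013	down	literature
rno-miR-127-3p	HJR2013	up	literature
rno-miR-129-1-3p	HF2020	down	literature
rno-miR-129-2-3p	WXY2019	down	literature
rno-miR-1298	HJR2013	down	literature
rno-miR-1306-5p	LXQ2016	down	literature
rno-miR-130b-3p	HJR2013	down	literature
rno-miR-132-5p	ZGL2020	up	literature
rno-miR-133a-5p	LY2018	up	literature
rno-miR-136-5p	LJA2016	up	literature
rno-miR-140-5p	LJA2016	up	literature
rno-miR-144-5p	LXQ2018	down	literature
rno-miR-146a-5p	LXQ2016	down	literature
rno-miR-148a-3p	LXQ2018	down	literature
rno-miR-149-5p	WXY2019	up	literature
rno-miR-154-3p	LJA2016	down	literature
rno-miR-155-3p	HJR2013	up	literature
rno-miR-181b-5p	LY2018	down	literature
rno-miR-182	LXQ2018	down	literature
rno-miR-183-3p	LJA2016	up	literature
rno-miR-1839-5p	WXY2019	down	literature
rno-miR-185-3p	HF2020	up	literature
rno-miR-186-3p	LXQ2018	up	literature
rno-miR-199a-3p	LL2015	down	literature
rno-miR-19a-3p	LL2015	down	literature
rno-miR-19b-3p	HJR2013	down	literature
rno-miR-200b-3p	LXQ2018	up	literature
rno-miR-201-5p	LY2018	down	literature
rno-miR-204-3p	HJR2013	up	literature
rno-miR-20b-5p	ZGL2020	down	literature
rno-miR-21-5p	WXY2019	down	literature
rno-miR-210-3p	LJA2016	down	literature
rno-miR-214-3p	LY2018	down	literature
rno-miR-22-3p	HF2020	up	literature
rno-miR-22-3p	LJA2016	up	literature
rno-miR-22-3p	ZGL2020	down	literature
rno-miR-28-5p	HF2020	down	literature
rno-miR-291a-3p	LJA2016	down	literature
rno-miR-30c-5p	LXQ2016	up	literature
rno-miR-320a	HJR2013	up	literature
rno-miR-323	LXQ2016	up	literature
rno-miR-330-5p	ZGL2020	up	literature
rno-miR-336-5p	LXQ2016	down	literature
rno-miR-339-5p	LY2018	up	literature
rno-miR-346	LXQ2016	up	literature
rno-miR-34c-3p	LXQ2016	up	literature
rno-miR-352	HJR2013	down	literature
rno-miR-3547	ZGL2020	down	literature
rno-miR-365-3p	LL2015	up	literature
rno-miR-369-5p	LXQ2018	up	literature
rno-miR-375-5p	ZGL2020	down	literature
rno-miR-376a-5p	HF2020	up	literature
rno-miR-376b-5p	LY2018	up	literature
rno-miR-377-5p	LXQ2016	down	literature
rno-miR-381-3p	HF2020	down	literature
rno-miR-463-3p	LL2015	up	literature
rno-miR-465-3p	WXY2019	up	literature
rno-miR-466c-5p	LY2018	up	literature
rno-miR-466d	HF2020	up	literature
rno-miR-487b-3p	LL2015	down	literature
rno-miR-493-5p	LXQ2018	down	literature
rno-miR-497-5p	LJA2016	down	literature
rno-miR-499-5p	HF2020	down	literature
rno-miR-505-5p	WXY2019	up	literature
rno-miR-542-5p	LXQ2018	down	literature
rno-miR-632	LXQ2016	down	literature
rno-miR-632	ZGL2020	up	literature
rno-miR-665	HJR2013	up	literature
rno-miR-672-3p	LJA2016	up	literature
rno-miR-675-5p	LL2015	up	literature
rno-miR-743a-3p	LL2015	down	literature
rno-miR-743b-3p	LXQ2016	down	literature
rno-miR-760-5p	LXQ2016	up	literature
rno-miR-873-5p	LXQ2018	up	literature
rno-miR-935	LL2015	up	literature
rno-miR-98-5p	LL2015	down	literature
rno-miR-99a-3p	ZGL2020	down	literature
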